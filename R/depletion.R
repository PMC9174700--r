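#' Linear (Whillans-Rauth) oxygen depletion model
#'
#' Radiolytic oxygen consumption proportional to delivered dose:
#' `o2(d) = max(o2_0 - rate * d, 0)`. Rates of 0.21-0.42 Torr/Gy have been
#' measured under conventional (Co-60, ~1 Gy/min) conditions; much steeper
#' effective rates (~15 Torr/Gy) are needed to reproduce ultra-high dose
#' rate cell experiments, so the rate is a free configuration value here.
#'
#' @param o2_0 initial partial oxygen pressure (Torr), >= 0.
#' @param rate depletion rate (Torr per Gy), >= 0.
#' @return an object of class `linear_depletion`.
#' @export
linear_depletion <- function(o2_0, rate) {
  .assert_scalar_number(o2_0, "o2_0", lower = 0)
  .assert_scalar_number(rate, "rate", lower = 0)
  structure(list(o2_0 = o2_0, rate = rate), class = "linear_depletion")
}

#' @export
print.linear_depletion <- function(x, ...) {
  cat(sprintf("Linear oxygen depletion: o2_0 = %g Torr, rate = %g Torr/Gy\n",
              x$o2_0, x$rate))
  invisible(x)
}

#' Instantaneous pO2 after a delivered dose (linear model)
#'
#' @param model a [linear_depletion()] model.
#' @param d cumulative delivered dose (Gy), >= 0; vectorised.
#' @return pO2 in Torr, clamped at 0.
#' @export
linear_o2_at_dose <- function(model, d) {
  if (!inherits(model, "linear_depletion")) {
    stop_config("'model' must be a linear_depletion object")
  }
  if (any(!is.finite(d) | d < 0)) stop_domain("dose must be finite and >= 0")
  pmax(model$o2_0 - model$rate * d, 0)
}

#' Depletion trajectory: pO2 as a function of cumulative dose
#'
#' A piecewise-linear, non-increasing map from cumulative dose (Gy) to
#' instantaneous pO2 (Torr). This is the "dose oxygen" view (DOH) from
#' which oxygen dose histograms are built.
#'
#' @param cum_dose_gy non-decreasing cumulative doses (Gy), starting at 0.
#' @param o2_torr non-increasing pO2 values (Torr), >= 0.
#' @return an object of class `depletion_trajectory` (a data frame).
#' @export
depletion_trajectory <- function(cum_dose_gy, o2_torr) {
  if (length(cum_dose_gy) < 2L || length(o2_torr) != length(cum_dose_gy)) {
    stop_config("need >= 2 breakpoints with matching lengths")
  }
  if (is.unsorted(cum_dose_gy)) stop_config("cumulative doses must be non-decreasing")
  if (any(o2_torr < 0)) stop_config("pO2 must be >= 0 along the trajectory")
  if (any(diff(o2_torr) > 1e-9 * max(o2_torr[1], 1))) {
    stop_config("trajectory pO2 must be non-increasing")
  }
  # snub out tiny numerical up-ticks so downstream binning sees a monotone curve
  o2_torr <- cummin(o2_torr)
  structure(
    data.frame(cum_dose_gy = cum_dose_gy, o2_torr = o2_torr),
    class = c("depletion_trajectory", "data.frame")
  )
}

#' Interpolate a trajectory at arbitrary cumulative doses
#'
#' @param traj a [depletion_trajectory()].
#' @param d cumulative doses (Gy) within the trajectory span.
#' @return interpolated pO2 (Torr).
#' @export
trajectory_o2 <- function(traj, d) {
  stats::approx(traj$cum_dose_gy, traj$o2_torr, xout = d, ties = "ordered")$y
}

#' Exact trajectory of the linear depletion model
#'
#' Breakpoints at dose 0, at the hypoxia-onset dose `o2_0 / rate` when it is
#' reached within `total_dose`, and at `total_dose`; the piecewise-linear
#' representation is exact.
#'
#' @param model a [linear_depletion()] model.
#' @param total_dose total delivered dose (Gy), > 0.
#' @return a [depletion_trajectory()].
#' @export
linear_trajectory <- function(model, total_dose) {
  if (!inherits(model, "linear_depletion")) {
    stop_config("'model' must be a linear_depletion object")
  }
  .assert_scalar_number(total_dose, "total_dose")
  if (total_dose <= 0) stop_domain("total_dose must be > 0")
  d <- 0
  o <- model$o2_0
  if (model$rate > 0 && model$o2_0 > 0) {
    d_hyp <- model$o2_0 / model$rate
    if (d_hyp < total_dose) {
      d <- c(d, d_hyp)
      o <- c(o, 0)
    }
  }
  d <- c(d, total_dose)
  o <- c(o, max(model$o2_0 - model$rate * total_dose, 0))
  depletion_trajectory(d, o)
}

#' Second-order (Ling) oxygen depletion model
#'
#' Oxygen binds to radiation-induced species in a second-order reaction.
#' A dose `dose_d` generates a species concentration `g_yield * dose_d`
#' (Torr-equivalent); oxygen and species are consumed pairwise at binding
#' rate `lam` (per Torr-equivalent per ns). The closed-form time course is
#' the solution of `dx/dt = -lam * x * (x + g_yield*dose_d - o2_0)`; when
#' the induced species exactly matches the initial oxygen the solution
#' degenerates to the equal-concentration limit `o2_0 / (1 + lam*o2_0*t)`.
#' Depletion can be incomplete: the long-time residual is
#' `max(o2_0 - g_yield * dose_d, 0)`.
#'
#' @param o2_0 initial pO2 (Torr), >= 0.
#' @param g_yield induced-species concentration per unit dose
#'   (Torr-equivalent per Gy), >= 0.
#' @param dose_d delivered dose (Gy), >= 0.
#' @param lam binding rate (per Torr-equivalent per ns), >= 0.
#' @return an object of class `ling_depletion`.
#' @export
ling_depletion <- function(o2_0, g_yield, dose_d, lam) {
  .assert_scalar_number(o2_0, "o2_0", lower = 0)
  .assert_scalar_number(g_yield, "g_yield", lower = 0)
  .assert_scalar_number(dose_d, "dose_d", lower = 0)
  .assert_scalar_number(lam, "lam", lower = 0)
  structure(list(o2_0 = o2_0, g_yield = g_yield, dose_d = dose_d, lam = lam),
            class = "ling_depletion")
}

#' @export
print.ling_depletion <- function(x, ...) {
  cat(sprintf(
    "Second-order oxygen depletion: o2_0 = %g Torr, G = %g Torr/Gy, D = %g Gy, lambda = %g /Torr/ns\n",
    x$o2_0, x$g_yield, x$dose_d, x$lam))
  invisible(x)
}

#' pO2 at time t under second-order depletion
#'
#' Numerically stable evaluation of the closed-form second-order solution.
#' Writing `gd = g_yield * dose_d` and `delta = o2_0 - gd`, the surplus
#' branch (`delta > 0`) is computed as
#' `o2_0 * (gd - o2_0) / (gd * exp(-lam*delta*t) - o2_0)` so the
#' exponential always decays; the deficit branch uses the mirrored form.
#' Within a relative tolerance of 1e-9 of `gd = o2_0` the analytic
#' equal-concentration limit is used to avoid 0/0 cancellation.
#'
#' @param model a [ling_depletion()] model.
#' @param t time since pulse start (ns), >= 0; vectorised.
#' @return pO2 in Torr.
#' @export
ling_o2_at_time <- function(model, t) {
  if (!inherits(model, "ling_depletion")) {
    stop_config("'model' must be a ling_depletion object")
  }
  if (any(t < 0)) stop_domain("time must be >= 0")
  x0 <- model$o2_0
  gd <- model$g_yield * model$dose_d
  lam <- model$lam
  if (x0 == 0) return(rep(0, length(t)))
  delta <- x0 - gd
  if (abs(delta) < 1e-9 * max(gd, x0)) {
    return(x0 / (1 + lam * x0 * t))
  }
  if (delta > 0) {
    # oxygen surplus: decays towards the residual x0 - gd
    x0 * (gd - x0) / (gd * exp(-lam * delta * t) - x0)
  } else {
    # species surplus: full depletion at long times
    e <- exp(lam * delta * t)
    x0 * (gd - x0) * e / (gd - x0 * e)
  }
}

#' Long-time oxygen residual of the second-order model
#'
#' @param model a [ling_depletion()] model.
#' @return `max(o2_0 - g_yield * dose_d, 0)` in Torr.
#' @export
ling_residual <- function(model) {
  if (!inherits(model, "ling_depletion")) {
    stop_config("'model' must be a ling_depletion object")
  }
  max(model$o2_0 - model$g_yield * model$dose_d, 0)
}

#' Dose-domain trajectory of the second-order model
#'
#' Samples the second-order time course at `n_steps` equispaced times over
#' one rectangular pulse and maps time to cumulative dose assuming a
#' constant in-pulse dose rate, `d = dose_d * t / pulse_length`.
#'
#' @param model a [ling_depletion()] model with `dose_d > 0`.
#' @param pulse_length_ns pulse length (ns), > 0.
#' @param n_steps number of samples, >= 2 (default 401).
#' @return a [depletion_trajectory()].
#' @export
ling_trajectory <- function(model, pulse_length_ns, n_steps = 401L) {
  .assert_scalar_number(pulse_length_ns, "pulse_length_ns")
  if (pulse_length_ns <= 0) stop_domain("pulse_length_ns must be > 0")
  if (n_steps < 2L) stop_domain("n_steps must be >= 2")
  if (model$dose_d <= 0) stop_domain("the model must carry a positive dose_d")
  t <- seq(0, pulse_length_ns, length.out = n_steps)
  o2 <- ling_o2_at_time(model, t)
  if (any(diff(o2) > 1e-9 * max(model$o2_0, 1))) {
    .fo_stop("second-order trajectory sampled non-monotone; numerical inconsistency",
             "flashodh_internal_error")
  }
  depletion_trajectory(model$dose_d * t / pulse_length_ns, o2)
}

#' Read / write depletion trajectories as CSV
#'
#' CSV layout: header `cum_dose_gy,o2_torr`.
#'
#' @param traj a [depletion_trajectory()].
#' @param path file path.
#' @return the reader returns a `depletion_trajectory`; the writer `path`,
#'   invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("cum_dose_gy", "o2_torr") %in% names(d))) {
    stop_config("expected CSV columns cum_dose_gy, o2_torr")
  }
  depletion_trajectory(d$cum_dose_gy, d$o2_torr)
}
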