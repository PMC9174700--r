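#' Radiation pulse
#'
#' A single beam pulse of length `length_ns` with either a constant
#' instantaneous dose rate (cGy/ns), a tabulated rate (data frame with
#' columns `t_ns`, `rate_cgy_ns`), or a rate function of time in ns
#' returning cGy/ns. Exactly one of `rate_cgy_ns`, `dose_gy` or `shape`
#' must be given; `dose_gy` is shorthand for the constant rate
#' `100 * dose_gy / length_ns`.
#'
#' @param length_ns pulse length (ns), > 0.
#' @param rate_cgy_ns constant instantaneous dose rate (cGy per ns), >= 0.
#' @param dose_gy total pulse dose (Gy) for a rectangular pulse.
#' @param shape tabulated or functional rate over `[0, length_ns]`.
#' @return an object of class `pulse`.
#' @examples
#' pulse(3400, dose_gy = 15)  # 15 Gy in 3.4 us -> ~0.441 cGy/ns
#' @export
pulse <- function(length_ns, rate_cgy_ns = NULL, dose_gy = NULL, shape = NULL) {
  .assert_scalar_number(length_ns, "length_ns")
  if (length_ns <= 0) stop_domain("pulse length must be > 0")
  given <- c(!is.null(rate_cgy_ns), !is.null(dose_gy), !is.null(shape))
  if (sum(given) != 1L) {
    stop_config("give exactly one of rate_cgy_ns, dose_gy or shape")
  }
  if (!is.null(dose_gy)) {
    .assert_scalar_number(dose_gy, "dose_gy", lower = 0)
    rate_cgy_ns <- 100 * dose_gy / length_ns
  }
  if (!is.null(rate_cgy_ns)) {
    .assert_scalar_number(rate_cgy_ns, "rate_cgy_ns", lower = 0)
    shape <- NULL
  } else if (is.data.frame(shape)) {
    if (!all(c("t_ns", "rate_cgy_ns") %in% names(shape))) {
      stop_config("tabulated shape needs columns t_ns, rate_cgy_ns")
    }
    if (any(shape$rate_cgy_ns < 0)) stop_domain("pulse rates must be >= 0")
    if (is.unsorted(shape$t_ns, strictly = TRUE)) {
      stop_config("shape times must be strictly increasing")
    }
  } else if (!is.function(shape)) {
    stop_config("'shape' must be a data frame or a function of time (ns)")
  }
  structure(list(length_ns = length_ns, rate_cgy_ns = rate_cgy_ns, shape = shape),
            class = "pulse")
}

#' @export
print.pulse <- function(x, ...) {
  if (!is.null(x$rate_cgy_ns)) {
    cat(sprintf("Rectangular pulse: %g ns at %g cGy/ns (%g Gy)\n",
                x$length_ns, x$rate_cgy_ns, pulse_dose(x)))
  } else {
    cat(sprintf("Shaped pulse: %g ns, %g Gy\n", x$length_ns, pulse_dose(x)))
  }
  invisible(x)
}

#' Total dose delivered by a pulse
#'
#' Integral of the instantaneous dose rate over the pulse: exact
#' `length * rate` for rectangular pulses (converted cGy to Gy), trapezoid
#' quadrature for tabulated shapes and adaptive quadrature for functional
#' shapes.
#'
#' @param p a [pulse()].
#' @return pulse dose in Gy.
#' @export
pulse_dose <- function(p) {
  if (!inherits(p, "pulse")) stop_config("'p' must be a pulse object")
  if (!is.null(p$rate_cgy_ns)) {
    return(p$length_ns * p$rate_cgy_ns / 100)
  }
  if (is.data.frame(p$shape)) {
    t <- p$shape$t_ns
    r <- p$shape$rate_cgy_ns
    return(sum(diff(t) * (r[-length(r)] + r[-1]) / 2) / 100)
  }
  rate <- p$shape
  if (any(rate(seq(0, p$length_ns, length.out = 257)) < 0)) {
    stop_domain("pulse rates must be >= 0")
  }
  stats::integrate(rate, 0, p$length_ns, rel.tol = 1e-9,
                   subdivisions = 500L)$value / 100
}

#' Pulse train
#'
#' A train of identical pulses delivered `period_ms` apart with a
#' re-oxygenation assumption between pulses: `"full"` (the tissue returns
#' to the baseline pO2 before every pulse), `"none"` (the next pulse starts
#' at the previous end level), or `"partial"` with recovery fraction
#' `fraction` of the depleted amount.
#'
#' @param p a [pulse()].
#' @param count number of pulses, >= 1.
#' @param period_ms time between pulse starts (ms); must exceed the pulse
#'   length.
#' @param reoxygenation one of `"full"`, `"none"`, `"partial"`.
#' @param fraction recovery fraction in `[0, 1]` when
#'   `reoxygenation = "partial"`.
#' @return an object of class `pulse_train`.
#' @export
pulse_train <- function(p, count = 1L, period_ms = 10,
                        reoxygenation = c("full", "none", "partial"),
                        fraction = NULL) {
  if (!inherits(p, "pulse")) stop_config("'p' must be a pulse object")
  reoxygenation <- match.arg(reoxygenation)
  .assert_scalar_number(count, "count", lower = 1)
  if (count != round(count)) stop_domain("count must be an integer")
  .assert_scalar_number(period_ms, "period_ms", lower = 0)
  if (period_ms * 1e6 < p$length_ns) {
    stop_config("pulse period must be at least the pulse length")
  }
  if (reoxygenation == "partial") {
    .assert_scalar_number(fraction, "fraction", lower = 0)
    if (fraction > 1) stop_domain("'fraction' must lie in [0, 1]")
  } else {
    fraction <- if (reoxygenation == "full") 1 else 0
  }
  structure(
    list(pulse = p, count = as.integer(count), period_ms = period_ms,
         reoxygenation = reoxygenation, fraction = fraction),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("Pulse train: %d x %g Gy pulses, period %g ms, re-oxygenation %s\n",
              x$count, pulse_dose(x$pulse), x$period_ms,
              if (x$reoxygenation == "partial")
                sprintf("partial (f = %g)", x$fraction) else x$reoxygenation))
  invisible(x)
}

#' Dose per pulse from a mean dose rate
#'
#' Converts a mean (macroscopic) dose rate in Gy/s into the dose delivered
#' within a single pulse by dividing by the pulse repetition frequency.
#' The per-pulse dose is what governs within-pulse oxygen depletion.
#'
#' @param mean_rate_gy_s mean dose rate (Gy per s).
#' @param prf_hz pulse repetition frequency (Hz), > 0.
#' @return dose per pulse in Gy; vectorised over `mean_rate_gy_s`.
#' @examples
#' dose_per_pulse(100, 100)  # 1 Gy per pulse
#' @export
dose_per_pulse <- function(mean_rate_gy_s, prf_hz) {
  .assert_scalar_number(prf_hz, "prf_hz")
  if (prf_hz <= 0) stop_domain("pulse repetition frequency must be > 0")
  if (any(mean_rate_gy_s < 0)) stop_domain("mean dose rate must be >= 0")
  mean_rate_gy_s / prf_hz
}

#' Oxygen dose histogram (ODH)
#'
#' Delivered dose binned by the instantaneous pO2 at which it was
#' deposited. Bins are left-closed right-open `[lo, hi)` on pO2 with the
#' lowest edge at exactly 0, so fully hypoxic dose occupies the first bin.
#' The histogram's total (the "area under the ODH") is the total delivered
#' dose, and ODHs are additive across pulses.
#'
#' Each bin also carries the exact dose-weighted mean pO2 of the dose it
#' holds (its first moment), so degenerate histograms — all dose at a single
#' level — evaluate exactly rather than at the bin midpoint.
#'
#' @param edges strictly increasing pO2 bin edges (Torr), first edge 0.
#' @param doses dose per bin (Gy), >= 0, length `length(edges) - 1`.
#' @param moment per-bin first moment `sum(dose * o2)` (Gy Torr); defaults
#'   to `doses * midpoints` (dose spread uniformly within each bin).
#' @return an object of class `odh`.
#' @seealso [odh_from_trajectory()], [odh_add()], [odh_scale()]
#' @export
odh <- function(edges, doses, moment = NULL) {
  if (length(edges) < 2L || length(doses) != length(edges) - 1L) {
    stop_config("need n+1 edges for n bins")
  }
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_config("bin edges must be strictly increasing")
  }
  if (edges[1] != 0) stop_config("the lowest pO2 edge must be exactly 0")
  if (any(doses < 0)) stop_config("bin doses must be >= 0")
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  if (is.null(moment)) {
    moment <- doses * mid
  } else {
    if (length(moment) != length(doses)) {
      stop_config("'moment' must have one entry per bin")
    }
    lo <- edges[-length(edges)]
    hi <- edges[-1]
    tol <- 1e-9 * pmax(doses * hi, 1e-300)
    if (any(moment < doses * lo - tol | moment > doses * hi + tol)) {
      stop_config("bin moments imply a mean pO2 outside the bin")
    }
  }
  structure(list(edges = as.numeric(edges), doses = as.numeric(doses),
                 moment = as.numeric(moment)),
            class = "odh")
}

#' Representative pO2 of each ODH bin
#'
#' The exact dose-weighted mean pO2 of the dose in each bin, falling back
#' to the bin midpoint for empty bins. This is the level at which each
#' bin's dose is evaluated by [total_damage()].
#'
#' @param x an [odh()].
#' @return representative pO2 values (Torr), one per bin.
#' @export
odh_reps <- function(x) {
  mid <- odh_midpoints(x)
  ifelse(x$doses > 0, x$moment / pmax(x$doses, 1e-300), mid)
}

#' Total dose carried by an ODH
#'
#' @param x an [odh()].
#' @return total dose in Gy.
#' @export
odh_total <- function(x) {
  if (!inherits(x, "odh")) stop_config("'x' must be an odh object")
  sum(x$doses)
}

#' Bin midpoints of an ODH
#'
#' The representative pO2 at which each bin's dose is evaluated downstream.
#'
#' @param x an [odh()].
#' @return midpoint pO2 values (Torr).
#' @export
odh_midpoints <- function(x) {
  (x$edges[-length(x$edges)] + x$edges[-1]) / 2
}

#' @export
print.odh <- function(x, ...) {
  occ <- sum(x$doses > 0)
  cat(sprintf("Oxygen dose histogram: %.6g Gy over [%g, %g) Torr (%d of %d bins occupied)\n",
              odh_total(x), x$edges[1], x$edges[length(x$edges)], occ,
              length(x$doses)))
  invisible(x)
}

#' @export
as.data.frame.odh <- function(x, ...) {
  data.frame(
    o2_lo_torr = x$edges[-length(x$edges)],
    o2_hi_torr = x$edges[-1],
    dose_gy = x$doses,
    o2_rep_torr = odh_reps(x)
  )
}

.default_edges <- function(max_o2, bin_width) {
  if (bin_width <= 0) stop_config("bin_width must be > 0")
  # top edge strictly above max_o2 so the starting level lies inside a bin
  n_bins <- max(1L, floor(max_o2 / bin_width + 1e-12) + 1L)
  seq(0, by = bin_width, length.out = n_bins + 1L)
}

#' Build an ODH from a depletion trajectory
#'
#' Integrates the dose deposited at each pO2 level exactly over the
#' piecewise-linear trajectory segments. For a purely linear depletion,
#' every fully traversed bin receives `bin_width / rate` Gy and the
#' hypoxic bin collects the remainder, reproducing the flat-topped
#' histogram of constant-rate depletion.
#'
#' @param traj a [depletion_trajectory()] defined on `[0, D]`, `D > 0`.
#' @param bin_width pO2 bin width (Torr), default 0.1.
#' @param edges explicit bin edges overriding `bin_width`; must start at 0
#'   and cover the trajectory's pO2 range.
#' @return an [odh()] whose total equals the trajectory's total dose to
#'   within floating-point round-off.
#' @export
odh_from_trajectory <- function(traj, bin_width = 0.1, edges = NULL) {
  if (!inherits(traj, "depletion_trajectory")) {
    stop_config("'traj' must be a depletion_trajectory")
  }
  total <- traj$cum_dose_gy[nrow(traj)] - traj$cum_dose_gy[1]
  if (total <= 0) stop_domain("trajectory must span a positive dose")
  o_max <- max(traj$o2_torr)
  if (is.null(edges)) {
    edges <- .default_edges(o_max, bin_width)
  } else {
    if (edges[1] != 0 || is.unsorted(edges, strictly = TRUE)) {
      stop_config("edges must start at 0 and increase strictly")
    }
    if (edges[length(edges)] < o_max) {
      stop_config("bin edges do not cover the trajectory's pO2 range")
    }
  }
  nb <- length(edges) - 1L
  doses <- numeric(nb)
  moment <- numeric(nb)
  d <- traj$cum_dose_gy
  o <- traj$o2_torr
  for (i in seq_len(length(d) - 1L)) {
    dd <- d[i + 1L] - d[i]
    if (dd <= 0) next
    o0 <- o[i]
    o1 <- o[i + 1L]
    if (o0 == o1) {
      # constant segment: all dose at a single level; top edge treated as
      # closed so a level sitting exactly on the last edge is kept
      j <- findInterval(o0, edges, rightmost.closed = TRUE)
      doses[j] <- doses[j] + dd
      moment[j] <- moment[j] + dd * o0
    } else {
      dens <- dd / (o0 - o1)  # Gy per Torr
      j0 <- findInterval(o1, edges)
      j1 <- min(findInterval(o0, edges, rightmost.closed = TRUE), nb)
      idx <- j0:j1
      up <- pmin(edges[idx + 1L], o0)
      dn <- pmax(edges[idx], o1)
      ov <- pmax(up - dn, 0)
      doses[idx] <- doses[idx] + dens * ov
      moment[idx] <- moment[idx] + dens * ov * (up + dn) / 2
    }
  }
  odh(edges, doses, moment)
}

#' Add two ODHs
#'
#' ODHs are additive: the histogram of a multi-pulse delivery is the sum of
#' the per-pulse histograms. Inputs on different grids are rebinned to the
#' union of their edges with exact mass-preserving reassignment (dose is
#' piecewise-uniform within a source bin).
#'
#' @param a,b [odh()] objects.
#' @return an [odh()] with total `odh_total(a) + odh_total(b)`.
#' @export
odh_add <- function(a, b) {
  if (!inherits(a, "odh") || !inherits(b, "odh")) {
    stop_config("both arguments must be odh objects")
  }
  edges <- sort(unique(c(a$edges, b$edges)))
  ra <- .rebin(a, edges)
  rb <- .rebin(b, edges)
  odh(edges, ra$doses + rb$doses, ra$moment + rb$moment)
}

# Redistribute x's bin doses (and first moments) onto a refined grid whose
# edges contain all of x's edges; each target bin lies inside exactly one
# source bin. Unsplit bins keep their exact moment; split bins fall back to
# the piecewise-uniform density assumption.
.rebin <- function(x, edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mid <- (lo + hi) / 2
  j <- findInterval(mid, x$edges)
  w_src <- diff(x$edges)
  doses <- numeric(length(mid))
  moment <- numeric(length(mid))
  inside <- j >= 1L & j <= length(x$doses) & mid < x$edges[length(x$edges)]
  ji <- j[inside]
  w_tgt <- (hi - lo)[inside]
  frac <- w_tgt / w_src[ji]
  doses[inside] <- x$doses[ji] * frac
  whole <- abs(frac - 1) < 1e-12
  m <- doses[inside] * mid[inside]      # split bins: uniform within source
  m[whole] <- x$moment[ji][whole]       # unsplit bins: exact moment
  moment[inside] <- m
  list(doses = doses, moment = moment)
}

#' Scale an ODH
#'
#' Multiplies every bin dose by `k`; `odh_scale(x, n)` is the histogram of
#' `n` identical pulses under full re-oxygenation.
#'
#' @param x an [odh()].
#' @param k positive scale factor.
#' @return an [odh()].
#' @export
odh_scale <- function(x, k) {
  if (!inherits(x, "odh")) stop_config("'x' must be an odh object")
  .assert_scalar_number(k, "k")
  if (k <= 0) stop_domain("'k' must be > 0")
  odh(x$edges, x$doses * k, x$moment * k)
}

# Single pulse of dose dpp starting at pO2 `start`; returns the ODH and the
# end-of-pulse oxygen level.
.single_pulse_odh <- function(model, start, dpp, length_ns, bin_width) {
  if (inherits(model, "linear_depletion")) {
    m <- linear_depletion(start, model$rate)
    traj <- linear_trajectory(m, dpp)
  } else if (inherits(model, "ling_depletion")) {
    m <- ling_depletion(start, model$g_yield, dpp, model$lam)
    traj <- ling_trajectory(m, length_ns)
  } else {
    stop_config("'model' must be a linear_depletion or ling_depletion object")
  }
  list(odh = odh_from_trajectory(traj, bin_width),
       o2_end = traj$o2_torr[nrow(traj)])
}

#' Compose the ODH of a pulse train
#'
#' Builds the ODH of `count` identical pulses under the train's
#' re-oxygenation assumption. Under full re-oxygenation every pulse has the
#' same oxygen signature and the single-pulse histogram is simply scaled by
#' the pulse count. With none or partial recovery, pulse `i + 1` starts at
#' `o2_end + f * (o2_0 - o2_end)` and the per-pulse histograms are added.
#' For the linear model with no re-oxygenation this reproduces exactly the
#' ODH of one continuous pulse carrying the whole dose.
#'
#' @param train a [pulse_train()].
#' @param model a [linear_depletion()] or [ling_depletion()] model supplying
#'   the baseline pO2 and depletion kinetics; for the second-order model the
#'   per-pulse dose replaces the model's `dose_d`.
#' @param bin_width pO2 bin width (Torr) for the histograms.
#' @return an [odh()] carrying `count * dose-per-pulse` Gy.
#' @export
compose_train <- function(train, model, bin_width = 0.1) {
  if (!inherits(train, "pulse_train")) {
    stop_config("'train' must be a pulse_train object")
  }
  dpp <- pulse_dose(train$pulse)
  if (dpp <= 0) stop_domain("pulses must carry positive dose")
  o2_0 <- model$o2_0
  if (train$fraction == 1) {
    sp <- .single_pulse_odh(model, o2_0, dpp, train$pulse$length_ns, bin_width)
    return(if (train$count == 1L) sp$odh else odh_scale(sp$odh, train$count))
  }
  start <- o2_0
  acc <- NULL
  for (i in seq_len(train$count)) {
    sp <- .single_pulse_odh(model, start, dpp, train$pulse$length_ns, bin_width)
    acc <- if (is.null(acc)) sp$odh else odh_add(acc, sp$odh)
    start <- sp$o2_end + train$fraction * (o2_0 - sp$o2_end)
  }
  acc
}

#' Read / write ODHs as CSV
#'
#' CSV layout: header `o2_lo_torr,o2_hi_torr,dose_gy`, one row per bin.
#'
#' @param x an [odh()].
#' @param path file path.
#' @return the reader returns an `odh`; the writer `path`, invisibly.
#' @export
write_odh <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_odh
#' @export
read_odh <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("o2_lo_torr", "o2_hi_torr", "dose_gy") %in% names(d))) {
    stop_config("expected CSV columns o2_lo_torr, o2_hi_torr, dose_gy")
  }
  if (any(abs(d$o2_lo_torr[-1] - d$o2_hi_torr[-nrow(d)]) > 1e-9)) {
    stop_config("ODH bins must be contiguous")
  }
  moment <- if ("o2_rep_torr" %in% names(d)) d$dose_gy * d$o2_rep_torr
  odh(c(d$o2_lo_torr, d$o2_hi_torr[nrow(d)]), d$dose_gy, moment)
}
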