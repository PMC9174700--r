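#' Total complex damage under an ODH
#'
#' Converts an oxygen dose histogram to a total complex-lesion count by
#' summing `dose_i * response(rep_i)` over the bins, where `rep_i` is the
#' bin's dose-weighted mean pO2 (see [odh_reps()]; the bin midpoint for
#' histograms built without sub-bin information). As the bin width shrinks
#' this converges (second order) to the exact integral of the damage
#' response along the depletion trajectory; for dose concentrated at a
#' single level it is exact at any bin width.
#'
#' @param x an [odh()].
#' @param params an [oxygen_response_params()] set; defaults to the 2 MeV
#'   electron parameters.
#' @return total lesions per cell per Gbp.
#' @export
total_damage <- function(x, params = default_response_params()) {
  if (!inherits(x, "odh")) stop_config("'x' must be an odh object")
  sum(x$doses * oxygen_response(odh_reps(x), params))
}

#' Closed-form damage integral for linear depletion
#'
#' For a single pulse of dose `dose` under linear depletion from `o2_0` at
#' `rate` Torr/Gy, the exact integral of the damage response along the
#' trajectory is `(1 / rate) * [c1 * (o2_0 - o2_end) -
#' (c1 * c3 - c2) * log((o2_0 + c3) / (o2_end + c3))]` over the oxygenated
#' stretch, plus `(dose - d_hyp) * c2 / c3` for any dose delivered after
#' hypoxia onset at `d_hyp = o2_0 / rate`. Used as the fast path for voxel
#' maps and as the internal oracle for the binned computation.
#'
#' @param o2_0 initial pO2 (Torr), >= 0; vectorised.
#' @param rate depletion rate (Torr/Gy), >= 0; vectorised.
#' @param dose delivered dose (Gy), >= 0; vectorised.
#' @param params an [oxygen_response_params()] set.
#' @return total lesions per cell per Gbp; inputs are recycled.
#' @export
linear_damage <- function(o2_0, rate, dose, params = default_response_params()) {
  if (any(o2_0 < 0) || any(rate < 0) || any(dose < 0)) {
    stop_domain("o2_0, rate and dose must all be >= 0")
  }
  n <- max(length(o2_0), length(rate), length(dose))
  o2_0 <- rep_len(o2_0, n)
  rate <- rep_len(rate, n)
  dose <- rep_len(dose, n)
  c1 <- params$c1; c2 <- params$c2; c3 <- params$c3
  o2_end <- pmax(o2_0 - rate * dose, 0)
  anti <- function(u) c1 * u + (c2 - c1 * c3) * log(u + c3)
  oxic <- ifelse(rate > 0, (anti(o2_0) - anti(o2_end)) / rate, 0)
  d_hyp <- ifelse(rate > 0, o2_0 / rate, Inf)
  hyp <- pmax(dose - d_hyp, 0) * (c2 / c3)
  ifelse(rate == 0, dose * oxygen_response(o2_0, params), oxic + hyp)
}

#' FLASH sparing factor of an ODH
#'
#' Ratio `M_D / M_D0` of the total complex damage under the histogram to
#' the damage that the same dose would inflict at the constant initial
#' oxygenation `o2_0`. For any trajectory that never exceeds `o2_0` the
#' factor lies in `(response(0)/response(o2_0), 1]`: values below 1
#' quantify the FLASH sparing effect.
#'
#' @param x an [odh()] with positive total dose.
#' @param o2_0 initial pO2 (Torr) defining the undepleted reference.
#' @param params an [oxygen_response_params()] set.
#' @return the dimensionless sparing factor.
#' @export
sparing_factor <- function(x, o2_0, params = default_response_params()) {
  total <- odh_total(x)
  if (total <= 0) stop_domain("the ODH must carry positive dose")
  total_damage(x, params) / (total * oxygen_response(o2_0, params))
}

#' Closed-form sparing factor for single-pulse linear depletion
#'
#' `linear_damage(...) / (dose * response(o2_0))`, exact for the linear
#' model with no binning error. Vectorised over all arguments.
#'
#' @inheritParams linear_damage
#' @return sparing factors in `(0, 1]`; exactly 1 where `rate == 0` or the
#'   depletion over `dose` is nil.
#' @export
sparing_factor_linear <- function(o2_0, rate, dose,
                                  params = default_response_params()) {
  if (any(dose <= 0)) stop_domain("dose must be > 0")
  linear_damage(o2_0, rate, dose, params) /
    (dose * oxygen_response(o2_0, params))
}

#' Full sparing summary of an ODH
#'
#' @param x an [odh()].
#' @param o2_0 initial pO2 (Torr).
#' @param params an [oxygen_response_params()] set.
#' @return a list of class `sparing_result` with `m_d` (damage under the
#'   ODH), `m_d0` (damage at constant `o2_0`), `factor = m_d / m_d0`,
#'   `total_dose` and `o2_0`.
#' @export
sparing_result <- function(x, o2_0, params = default_response_params()) {
  total <- odh_total(x)
  if (total <= 0) stop_domain("the ODH must carry positive dose")
  m_d <- total_damage(x, params)
  m_d0 <- total * oxygen_response(o2_0, params)
  structure(
    list(m_d = m_d, m_d0 = m_d0, factor = m_d / m_d0,
         total_dose = total, o2_0 = o2_0),
    class = "sparing_result"
  )
}

#' @export
print.sparing_result <- function(x, ...) {
  cat(sprintf(
    "FLASH sparing: F = %.4f (M_D = %.4g, M_D0 = %.4g lesions/cell/Gbp; %g Gy at o2_0 = %g Torr)\n",
    x$factor, x$m_d, x$m_d0, x$total_dose, x$o2_0))
  invisible(x)
}

#' Correct a measured survival fraction for FLASH sparing
#'
#' Rescales the killed fraction by the sparing factor:
#' `sf_corr = 1 - (1 - sf_meas) * factor`. With `factor = 1` (no sparing)
#' the survival is unchanged; smaller factors move the corrected survival
#' upward, never below the measured value.
#'
#' @param sf_meas measured surviving fraction in `[0, 1]`; vectorised.
#' @param factor sparing factor in `[0, 1]`; vectorised.
#' @return corrected surviving fraction in `[sf_meas, 1]`.
#' @export
correct_survival <- function(sf_meas, factor) {
  if (any(sf_meas < 0 | sf_meas > 1)) {
    stop_domain("surviving fractions must lie in [0, 1]")
  }
  if (any(factor < 0 | factor > 1)) {
    stop_domain("sparing factors must lie in [0, 1]")
  }
  1 - (1 - sf_meas) * factor
}

#' Sparing-factor sweeps over dose and initial oxygenation
#'
#' Single-pulse sparing factors under linear depletion across a dose grid
#' at fixed initial oxygenation (`sparing_vs_dose`) or across an
#' oxygenation grid at fixed dose (`sparing_vs_o2`). The `relative_sparing`
#' column reports `1 - factor`, the figure-style "relative sparing effect".
#'
#' @param doses dose grid (Gy), > 0.
#' @param o2_grid initial oxygenation grid (Torr), >= 0.
#' @param o2_0 fixed initial pO2 (Torr) for the dose sweep.
#' @param dose fixed dose (Gy) for the oxygenation sweep.
#' @param rate linear depletion rate (Torr/Gy).
#' @param params an [oxygen_response_params()] set.
#' @param method `"closed_form"` (exact linear-trajectory integral, default)
#'   or `"odh"` (binned histogram path).
#' @param bin_width pO2 bin width for `method = "odh"`.
#' @return a data frame with columns `dose_gy`, `o2_torr`,
#'   `sparing_factor`, `relative_sparing`.
#' @export
sparing_vs_dose <- function(doses, o2_0, rate,
                            params = default_response_params(),
                            method = c("closed_form", "odh"),
                            bin_width = 0.1) {
  method <- match.arg(method)
  if (length(doses) == 0L) stop_domain("empty dose grid")
  f <- if (method == "closed_form") {
    sparing_factor_linear(o2_0, rate, doses, params)
  } else {
    vapply(doses, function(D) {
      sparing_factor(
        odh_from_trajectory(linear_trajectory(linear_depletion(o2_0, rate), D),
                            bin_width),
        o2_0, params)
    }, numeric(1))
  }
  data.frame(dose_gy = doses, o2_torr = o2_0, sparing_factor = f,
             relative_sparing = 1 - f)
}

#' @rdname sparing_vs_dose
#' @export
sparing_vs_o2 <- function(o2_grid, dose, rate,
                          params = default_response_params(),
                          method = c("closed_form", "odh"),
                          bin_width = 0.1) {
  method <- match.arg(method)
  if (length(o2_grid) == 0L) stop_domain("empty oxygenation grid")
  f <- if (method == "closed_form") {
    sparing_factor_linear(o2_grid, rate, dose, params)
  } else {
    vapply(o2_grid, function(o2) {
      sparing_factor(
        odh_from_trajectory(linear_trajectory(linear_depletion(o2, rate), dose),
                            bin_width),
        o2, params)
    }, numeric(1))
  }
  data.frame(dose_gy = dose, o2_torr = o2_grid, sparing_factor = f,
             relative_sparing = 1 - f)
}

#' Dose at which two sparing curves cross
#'
#' At low doses a poorly oxygenated tissue is spared more than a
#' well-oxygenated one; at high doses the ordering reverses because the
#' asymptotic factors `response(0)/response(o2_0)` order the other way.
#' The crossover dose where the single-pulse linear-depletion sparing
#' curves at `o2_a` and `o2_b` intersect is found by root bracketing on
#' the closed-form difference.
#'
#' @param o2_a,o2_b the two initial oxygenation levels (Torr).
#' @param rate linear depletion rate (Torr/Gy), > 0.
#' @param bracket dose interval (Gy) searched for the crossing.
#' @param tol dose tolerance (Gy) of the root.
#' @param params an [oxygen_response_params()] set.
#' @return the crossover dose in Gy, or `NA` (with attribute
#'   `no_crossover = TRUE`) when the curves do not change order across the
#'   bracket. The no-crossover outcome is a regular result, not an error.
#' @export
crossover_dose <- function(o2_a, o2_b, rate, bracket = c(0.01, 1e4),
                           tol = 1e-6, params = default_response_params()) {
  .assert_scalar_number(rate, "rate")
  if (rate <= 0) stop_domain("'rate' must be > 0 for a crossover to exist")
  g <- function(D) {
    sparing_factor_linear(o2_a, rate, D, params) -
      sparing_factor_linear(o2_b, rate, D, params)
  }
  g_lo <- g(bracket[1])
  g_hi <- g(bracket[2])
  if (!is.finite(g_lo) || !is.finite(g_hi) || g_lo * g_hi >= 0) {
    return(structure(NA_real_, no_crossover = TRUE))
  }
  stats::uniroot(g, interval = bracket, tol = tol)$root
}
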