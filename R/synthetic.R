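#' Synthetic damage-response table
#'
#' Generates (pO2, yield) points from the closed-form damage response with
#' optional additive Gaussian noise — the shape of Monte Carlo
#' damage-simulation tables that the response model is fitted to. A pure
#' function of its arguments including the seed.
#'
#' @param params an [oxygen_response_params()] set to sample from.
#' @param o2 pO2 grid (Torr); the default spans hypoxia to atmospheric.
#' @param noise_sd additive Gaussian noise standard deviation, either a
#'   single absolute value or (with `relative = TRUE`) a fraction of each
#'   true yield.
#' @param relative interpret `noise_sd` as a fraction of the true yield.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return a data frame with columns `o2_torr`, `yield`.
#' @export
gen_response_table <- function(params = default_response_params(),
                               o2 = c(0, 0.5, 1, 2, 3, 5, 7.6, 10, 15, 20,
                                      30, 50, 76, 110, 152),
                               noise_sd = 0, relative = FALSE, seed = NULL) {
  if (length(o2) == 0L) stop_domain("empty pO2 grid")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  y <- oxygen_response(o2, params)
  if (noise_sd > 0) {
    sd <- if (relative) noise_sd * y else rep(noise_sd, length(y))
    y <- with_seed(seed, y + stats::rnorm(length(y), sd = sd))
  }
  data.frame(o2_torr = o2, yield = y)
}

#' Synthetic single/double-pulse survival records
#'
#' Builds survival records with a known ground truth for round-trip testing
#' of [town_pipeline()]. Single-pulse survival follows the linear-quadratic
#' model on the effective dose, `SF_1(D) = exp(-alpha * D_eff - beta *
#' D_eff^2)` with `D_eff = D * F_1(D)`; double-pulse measured survival is
#' derived by inverting the killed-fraction correction,
#' `SF_2 = 1 - (1 - SF_1) / F_2`, so that the pipeline's correction restores
#' the single-pulse curve exactly. The LQ parameters are a fixture
#' convention (generic mammalian-cell scale), not a modelling claim.
#'
#' The inversion is only defined while `SF_1(D) >= 1 - F_2(D)`; at higher
#' doses the implied double-pulse survival would be negative. Doses where
#' this happens are dropped with a message and recorded in the
#' `dropped_doses` attribute.
#'
#' @param doses total doses (Gy); the default grid spans 0.5-45 Gy.
#' @param alpha,beta LQ coefficients (per Gy, per Gy^2).
#' @param o2_0 initial oxygenation (Torr).
#' @param rate effective linear depletion rate (Torr/Gy).
#' @param pulse_length_ns pulse length (ns).
#' @param bin_width pO2 bin width (Torr); must match the pipeline run.
#' @param noise_cv lognormal multiplicative noise coefficient of variation
#'   on the measured survival (0 = noiseless).
#' @param seed RNG seed.
#' @param params an [oxygen_response_params()] set.
#' @return a data frame with columns `dose_gy`, `sf_meas`, `n_pulses` and
#'   the ground-truth column `sf_true` (the noiseless single-pulse
#'   equivalent), plus attribute `dropped_doses`.
#' @export
gen_town_survival <- function(doses = exp(seq(log(0.5), log(45), length.out = 10)),
                              alpha = 0.3, beta = 0.03,
                              o2_0 = 152, rate = 15.0,
                              pulse_length_ns = 1200, bin_width = 0.1,
                              noise_cv = 0, seed = NULL,
                              params = default_response_params()) {
  if (any(doses <= 0)) stop_domain("doses must be > 0")
  if (noise_cv < 0) stop_domain("noise_cv must be >= 0")
  model <- linear_depletion(o2_0, rate)
  spar <- function(D, n) {
    train <- pulse_train(pulse(pulse_length_ns, dose_gy = D / n), count = n,
                         period_ms = 2.5, reoxygenation = "full")
    sparing_factor(compose_train(train, model, bin_width), o2_0, params)
  }
  f1 <- vapply(doses, spar, numeric(1), n = 1L)
  f2 <- vapply(doses, spar, numeric(1), n = 2L)
  sf1 <- exp(-alpha * doses * f1 - beta * (doses * f1)^2)
  sf2 <- 1 - (1 - sf1) / f2
  feasible <- sf2 >= 0
  if (!all(feasible)) {
    message(sprintf(
      "dropping %d dose(s) where the double-pulse inversion is infeasible (SF_1 < 1 - F_2): %s",
      sum(!feasible), paste(signif(doses[!feasible], 4), collapse = ", ")))
  }
  d_ok <- doses[feasible]
  rec <- data.frame(
    dose_gy = c(d_ok, d_ok),
    sf_meas = c(sf1[feasible], sf2[feasible]),
    n_pulses = rep(c(1L, 2L), each = length(d_ok)),
    sf_true = c(sf1[feasible], sf1[feasible])
  )
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rec$sf_meas <- with_seed(seed, {
      pmin(pmax(rec$sf_meas * stats::rlnorm(nrow(rec), -sdlog^2 / 2, sdlog), 0), 1)
    })
  }
  attr(rec, "dropped_doses") <- doses[!feasible]
  rec
}

#' Synthetic dose-rate sweep with linked behavioural responses
#'
#' Builds the arm table of a dose-rate sweep (the pre-clinical design:
#' nine pulsed arms at 0.1-500 Gy/s plus a single-pulse arm) and responses
#' generated as `baseline + slope * inverse_sparing + Gaussian noise`,
#' where the inverse sparing is computed by the physics path itself. With
#' zero noise the pipeline's rank correlation is exactly 1; with
#' `slope = 0` responses are pure noise and rho is null-distributed.
#'
#' @param dose_rates mean dose rates (Gy/s) of the pulsed arms.
#' @param include_single_pulse add a single-pulse arm delivering the full
#'   dose in one pulse (labelled by convention at 1000 Gy/s).
#' @param baseline response intercept.
#' @param slope effect-link slope from inverse sparing to response.
#' @param noise_sd Gaussian response noise standard deviation.
#' @param seed RNG seed.
#' @param dose total dose (Gy).
#' @param prf_hz pulse repetition frequency (Hz).
#' @param o2_0 initial oxygenation (Torr).
#' @param rate effective linear depletion rate (Torr/Gy).
#' @param pulse_length_ns pulse length (ns).
#' @param bin_width pO2 bin width (Torr).
#' @param params an [oxygen_response_params()] set.
#' @return an arm data frame ready for [recognition_pipeline()], with
#'   columns `label`, `mean_rate_gy_s`, `single_pulse`, `response`.
#' @export
gen_recognition_sweep <- function(dose_rates = c(0.1, 1, 3, 10, 20, 30, 60, 100, 500),
                                  include_single_pulse = TRUE,
                                  baseline = 0.5, slope = 0.1, noise_sd = 0,
                                  seed = NULL, dose = 10, prf_hz = 100,
                                  o2_0 = 20, rate = 15.0,
                                  pulse_length_ns = 1800, bin_width = 0.1,
                                  params = default_response_params()) {
  if (any(dose_rates <= 0)) stop_domain("dose rates must be > 0")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  arms <- data.frame(
    label = c(paste0(dose_rates, " Gy/s"),
              if (include_single_pulse) "1 pulse"),
    mean_rate_gy_s = c(dose_rates, if (include_single_pulse) dose / (pulse_length_ns * 1e-9)),
    single_pulse = c(rep(FALSE, length(dose_rates)), if (include_single_pulse) TRUE)
  )
  base <- recognition_pipeline(arms, dose = dose, prf_hz = prf_hz, o2_0 = o2_0,
                               rate = rate, pulse_length_ns = pulse_length_ns,
                               bin_width = bin_width, params = params)
  mu <- baseline + slope * base$arms$inverse_sparing
  arms$response <- if (noise_sd > 0) {
    with_seed(seed, mu + stats::rnorm(nrow(arms), sd = noise_sd))
  } else {
    mu
  }
  arms
}

#' Synthetic two-region phantom
#'
#' Dose and oxygenation voxel grids with a spherical core inside a shell —
#' e.g. a hypoxic core (2 Torr) in well-oxygenated surroundings (20 Torr).
#' Optional Gaussian noise produces smoothly varying fields; with zero
#' noise the grids take exactly the two configured values. Pure function of
#' its arguments including the seed.
#'
#' @param shape grid dimensions, 3 positive integers.
#' @param core_o2,shell_o2 pO2 (Torr) of core and shell.
#' @param core_dose,shell_dose dose (Gy) of core and shell.
#' @param core_radius core radius as a fraction of the smallest half-extent.
#' @param spacing voxel spacing (mm).
#' @param noise_sd additive Gaussian noise on both grids (truncated at 0).
#' @param seed RNG seed.
#' @return a list with `voxel_grid` elements `dose` and `o2`.
#' @export
gen_phantom <- function(shape = c(32, 32, 32), core_o2 = 2, shell_o2 = 20,
                        core_dose = 15, shell_dose = 15, core_radius = 0.4,
                        spacing = c(2, 2, 2), noise_sd = 0, seed = NULL) {
  if (length(shape) != 3L || any(shape < 1)) {
    stop_domain("'shape' must be 3 positive integers")
  }
  ctr <- (shape + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - ctr[k]) / (shape[k] / 2))
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  core <- r2 <= core_radius^2
  o2 <- array(shell_o2, shape)
  o2[core] <- core_o2
  dose <- array(shell_dose, shape)
  dose[core] <- core_dose
  if (noise_sd > 0) {
    noisy <- with_seed(seed, list(
      o2 = pmax(o2 + stats::rnorm(length(o2), sd = noise_sd), 0),
      dose = pmax(dose + stats::rnorm(length(dose), sd = noise_sd), 0)
    ))
    o2 <- array(noisy$o2, shape)
    dose <- array(noisy$dose, shape)
  }
  list(dose = voxel_grid(dose, spacing), o2 = voxel_grid(o2, spacing))
}
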