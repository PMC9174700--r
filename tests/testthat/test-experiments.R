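test_that("double-pulse sparing equals the single-pulse factor at half dose", {
  rec <- data.frame(dose_gy = c(10, 10), sf_meas = c(0.2, 0.15),
                    n_pulses = c(1L, 2L))
  out <- town_pipeline(rec)
  f_half <- sparing_factor(
    odh_from_trajectory(linear_trajectory(linear_depletion(152, 15), 5)), 152)
  expect_equal(out$sparing_factor[2], f_half, tolerance = 1e-12)
  expect_gt(out$sparing_factor[2], out$sparing_factor[1])  # halves deplete less
  # single-pulse records keep their measured survival
  expect_equal(out$sf_corr[1], out$sf_meas[1])
  expect_equal(out$sf_corr[2],
               correct_survival(out$sf_meas[2], out$sparing_factor[2]))
})

test_that("sparing decreases monotonically across the 0.5-45 Gy dose range", {
  doses <- c(0.5, 1, 2, 5, 10, 20, 30, 45)
  rec <- data.frame(dose_gy = doses, sf_meas = 0.5, n_pulses = 1L)
  out <- town_pipeline(rec)
  expect_true(all(diff(out$sparing_factor) < 0))
  expect_gt(out$sparing_factor[1], 0.95)  # 0.5 Gy: essentially no FLASH effect
})

test_that("zero depletion rate forces F = 1 and leaves survival untouched", {
  rec <- data.frame(dose_gy = c(2, 8, 8), sf_meas = c(0.8, 0.3, 0.25),
                    n_pulses = c(1L, 1L, 2L))
  out <- town_pipeline(rec, rate = 0)
  expect_equal(out$sparing_factor, rep(1, 3))
  expect_equal(out$sf_corr, out$sf_meas)
})

test_that("pipeline validates its record table", {
  expect_error(town_pipeline(data.frame(dose_gy = 1, sf_meas = 0.5, n_pulses = 3L)),
               class = "flashodh_domain_error")
  expect_error(town_pipeline(data.frame(dose_gy = -1, sf_meas = 0.5, n_pulses = 1L)),
               class = "flashodh_domain_error")
  expect_error(town_pipeline(data.frame(x = 1)), class = "flashodh_config_error")
})

test_that("synthetic double-pulse records round-trip to the single-pulse curve", {
  rec <- gen_town_survival(noise_cv = 0)
  out <- town_pipeline(rec)
  dbl <- out$n_pulses == 2L
  expect_gt(sum(dbl), 2L)
  expect_equal(out$sf_corr[dbl], out$sf_true[dbl], tolerance = 1e-12)
  # single-pulse records already sit on the curve by construction
  expect_equal(out$sf_corr[!dbl], out$sf_true[!dbl], tolerance = 1e-12)
})

test_that("pipelines are pure: identical inputs give identical outputs", {
  rec <- gen_town_survival(noise_cv = 0.05, seed = 42)
  rec2 <- gen_town_survival(noise_cv = 0.05, seed = 42)
  expect_identical(rec, rec2)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_survival_records(town_pipeline(rec), f1)
  write_survival_records(town_pipeline(rec2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("inverse sparing rises with mean dose rate in the sweep pipeline", {
  arms <- gen_recognition_sweep(noise_sd = 0)
  res <- recognition_pipeline(arms)
  pulsed <- !res$arms$single_pulse
  ord <- order(res$arms$mean_rate_gy_s[pulsed])
  expect_true(all(diff(res$arms$inverse_sparing[pulsed][ord]) > 0))
  # the single-pulse arm has the largest per-pulse dose, hence most sparing
  expect_equal(res$arms$dpp_gy[res$arms$single_pulse], 10)
  expect_gte(max(res$arms$inverse_sparing),
             max(res$arms$inverse_sparing[pulsed]))
  # at 0.1 Gy/s the per-pulse dose is 1 mGy and sparing is negligible
  expect_gt(res$arms$sparing_factor[res$arms$mean_rate_gy_s == 0.1], 0.99)
})

test_that("noiseless linked responses give perfect exact concordance", {
  arms <- gen_recognition_sweep(noise_sd = 0)
  res <- recognition_pipeline(arms)
  expect_equal(res$correlation$rho, 1)
  expect_equal(res$correlation$p_upper, 1 / factorial(10))
  expect_true(res$correlation$significant)
  expect_equal(res$correlation$critical$rho_c, 0.794)
})

test_that("arm tables validate and round-trip through CSV", {
  arms <- gen_recognition_sweep(noise_sd = 0.05, seed = 3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(arms, f, row.names = FALSE)
  back <- read_dose_rate_arms(f)
  expect_equal(back$mean_rate_gy_s, arms$mean_rate_gy_s)
  res <- recognition_pipeline(back)
  expect_equal(nrow(res$arms), 10)
  expect_error(recognition_pipeline(data.frame(label = "a", mean_rate_gy_s = -1)),
               class = "flashodh_domain_error")
})
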