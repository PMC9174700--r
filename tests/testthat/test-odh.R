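test_that("pulse dose integrates the instantaneous rate", {
  # 15 Gy in a 3.4 us pulse -> ~0.4412 cGy/ns constant rate
  p <- pulse(3400, dose_gy = 15)
  expect_equal(p$rate_cgy_ns, 1500 / 3400)
  expect_equal(pulse_dose(p), 15)
  expect_equal(pulse_dose(pulse(1e-9, rate_cgy_ns = 1)), 1e-11)  # zero-length limit

  # triangular tabulated shape: area L * peak / 2
  tri <- data.frame(t_ns = c(0, 1700, 3400), rate_cgy_ns = c(0, 2, 0))
  expect_equal(pulse_dose(pulse(3400, shape = tri)), 3400 * 2 / 2 / 100)

  # smooth functional shape vs analytic area
  p_fun <- pulse(1000, shape = function(t) sin(pi * t / 1000))
  expect_equal(pulse_dose(p_fun), (2000 / pi) / 100, tolerance = 1e-6)

  expect_error(pulse(3400, shape = data.frame(t_ns = c(0, 1), rate_cgy_ns = c(-1, 1))),
               class = "flashodh_domain_error")
  expect_error(pulse(0, dose_gy = 1), class = "flashodh_domain_error")
})

test_that("dose per pulse divides the mean rate by the repetition frequency", {
  expect_equal(dose_per_pulse(100, 100), 1)
  expect_equal(dose_per_pulse(0.1, 100), 0.001)
  expect_equal(dose_per_pulse(250, 250), 1)
  expect_error(dose_per_pulse(10, 0), class = "flashodh_domain_error")
})

test_that("linear-depletion ODH has flat bins plus a hypoxic remainder", {
  # 7 Torr at 0.6 Torr/Gy delivering 15 Gy on 1-Torr bins: every traversed
  # bin holds 1/0.6 Gy, the hypoxic bin additionally the post-onset dose
  tr <- linear_trajectory(linear_depletion(7, 0.6), 15)
  h <- odh_from_trajectory(tr, edges = 0:8)
  expect_equal(h$doses[2:7], rep(1 / 0.6, 6))
  expect_equal(h$doses[1], 1 / 0.6 + (15 - 7 / 0.6))
  expect_equal(h$doses[8], 0)
  expect_equal(odh_total(h), 15, tolerance = 1e-12)
})

test_that("a constant trajectory concentrates all dose in one bin", {
  tr <- linear_trajectory(linear_depletion(7, 0), 10)
  h <- odh_from_trajectory(tr, bin_width = 1)
  expect_equal(sum(h$doses > 0), 1L)
  j <- which(h$doses > 0)
  expect_true(h$edges[j] <= 7 && 7 < h$edges[j + 1])
  expect_equal(h$doses[j], 10)
})

test_that("ODH construction conserves dose over varied scenarios", {
  set.seed(401)
  for (i in 1:12) {
    o2_0 <- runif(1, 0.5, 160)
    rate <- runif(1, 0, 20)
    dose <- runif(1, 0.2, 50)
    tr <- linear_trajectory(linear_depletion(o2_0, rate), dose)
    h <- odh_from_trajectory(tr, bin_width = 0.1)
    expect_equal(odh_total(h), dose, tolerance = 1e-9)
  }
  m <- ling_depletion(20, 2, 12, 1e-3)
  expect_equal(odh_total(odh_from_trajectory(ling_trajectory(m, 3400))), 12,
               tolerance = 1e-9)
})

test_that("edges must start at zero and cover the trajectory", {
  tr <- linear_trajectory(linear_depletion(7, 0.6), 15)
  expect_error(odh_from_trajectory(tr, edges = c(0, 2, 5)),
               class = "flashodh_config_error")
  expect_error(odh_from_trajectory(tr, edges = c(1, 5, 10)),
               class = "flashodh_config_error")
  expect_error(odh(c(0, 1, 2), c(-1, 1)), class = "flashodh_config_error")
})

test_that("ODH addition is commutative, has an identity, and rebins exactly", {
  a <- odh_from_trajectory(linear_trajectory(linear_depletion(7, 0.6), 15),
                           bin_width = 0.5)
  empty <- odh(a$edges, rep(0, length(a$doses)))
  expect_equal(odh_add(a, empty)$doses, a$doses)
  expect_equal(odh_add(a, a)$doses, odh_scale(a, 2)$doses)

  b <- odh_from_trajectory(linear_trajectory(linear_depletion(20, 2), 8),
                           bin_width = 0.3)
  ab <- odh_add(a, b)
  ba <- odh_add(b, a)
  expect_equal(ab$edges, ba$edges)
  expect_equal(ab$doses, ba$doses, tolerance = 1e-12)
  expect_equal(odh_total(ab), odh_total(a) + odh_total(b), tolerance = 1e-12)

  # associativity up to rebinning round-off
  c_ <- odh_from_trajectory(linear_trajectory(linear_depletion(3, 1), 5),
                            bin_width = 0.7)
  l <- odh_add(odh_add(a, b), c_)
  r <- odh_add(a, odh_add(b, c_))
  expect_equal(l$doses, r$doses, tolerance = 1e-12)
})

test_that("scaling multiplies dose and inverts doubling", {
  a <- odh_from_trajectory(linear_trajectory(linear_depletion(7, 0.6), 1))
  expect_equal(odh_scale(a, 1)$doses, a$doses)
  expect_equal(odh_total(odh_scale(a, 3)), 3 * odh_total(a))
  expect_equal(odh_scale(odh_add(a, a), 0.5)$doses, a$doses)
  expect_error(odh_scale(a, 0), class = "flashodh_domain_error")
})

test_that("full re-oxygenation composes as count x single-pulse histogram", {
  m <- linear_depletion(152, 15)
  two <- pulse_train(pulse(1200, dose_gy = 7.5), count = 2, period_ms = 2.5,
                     reoxygenation = "full")
  h2 <- compose_train(two, m)
  h_single <- odh_from_trajectory(linear_trajectory(linear_depletion(152, 15), 7.5))
  expect_equal(h2$doses, odh_scale(h_single, 2)$doses, tolerance = 1e-12)
  expect_equal(odh_total(h2), 15, tolerance = 1e-9)
})

test_that("no re-oxygenation under linear depletion equals one long pulse", {
  m <- linear_depletion(20, 2)
  train <- pulse_train(pulse(1000, dose_gy = 3), count = 4, period_ms = 1,
                       reoxygenation = "none")
  h_train <- compose_train(train, m, bin_width = 0.25)
  h_long <- odh_from_trajectory(linear_trajectory(m, 12), bin_width = 0.25)
  expect_equal(h_train$edges, h_long$edges)
  expect_equal(h_train$doses, h_long$doses, tolerance = 1e-12)
})

test_that("partial re-oxygenation endpoints reproduce full and none", {
  m <- linear_depletion(20, 2)
  mk <- function(reox, f = NULL) {
    compose_train(pulse_train(pulse(1000, dose_gy = 3), count = 3,
                              period_ms = 1, reoxygenation = reox,
                              fraction = f),
                  m, bin_width = 0.25)
  }
  expect_equal(mk("partial", 1)$doses, mk("full")$doses, tolerance = 1e-12)
  expect_equal(mk("partial", 0)$doses, mk("none")$doses, tolerance = 1e-12)
  # intermediate recovery sits between the endpoint histograms in total damage
  d_full <- total_damage(mk("full"))
  d_none <- total_damage(mk("none"))
  d_half <- total_damage(mk("partial", 0.5))
  expect_true(d_half > min(d_none, d_full) - 1e-9)
  expect_true(d_half < max(d_none, d_full) + 1e-9)
})

test_that("ODH CSV round-trips bins and doses", {
  h <- odh_from_trajectory(linear_trajectory(linear_depletion(7, 0.6), 15),
                           bin_width = 0.5)
  f <- tempfile(fileext = ".csv")
  write_odh(h, f)
  h2 <- read_odh(f)
  expect_equal(h2$edges, h$edges)
  expect_equal(h2$doses, h$doses)
})
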