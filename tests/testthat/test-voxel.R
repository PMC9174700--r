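test_that("uniform grids reproduce the scalar result everywhere", {
  dose <- voxel_grid(array(15, c(4, 4, 4)))
  o2 <- voxel_grid(array(20, c(4, 4, 4)))
  maps <- voxel_sparing_map(dose, o2, rate = 15)
  f_scalar <- sparing_factor_linear(20, 15, 15)
  expect_equal(as.vector(maps$sparing$values), rep(f_scalar, 64),
               tolerance = 1e-12)
  expect_equal(as.vector(maps$damage$values), rep(linear_damage(20, 15, 15), 64),
               tolerance = 1e-12)
})

test_that("a two-region phantom yields exactly two sparing values", {
  ph <- gen_phantom(shape = c(12, 12, 12), core_o2 = 2, shell_o2 = 20,
                    core_dose = 15, shell_dose = 15)
  maps <- voxel_sparing_map(ph$dose, ph$o2, rate = 0.42)
  u <- sort(unique(as.vector(maps$sparing$values)))
  expect_length(u, 2L)
  expect_equal(u, sort(sparing_factor_linear(c(2, 20), 0.42, 15)),
               tolerance = 1e-12)
})

test_that("the histogram method agrees with the scalar ODH API per voxel", {
  ph <- gen_phantom(shape = c(6, 6, 6), core_o2 = 2, shell_o2 = 20)
  maps <- voxel_sparing_map(ph$dose, ph$o2, rate = 0.42, method = "odh",
                           bin_width = 0.05)
  for (o2v in c(2, 20)) {
    f_scalar <- sparing_factor(
      odh_from_trajectory(linear_trajectory(linear_depletion(o2v, 0.42), 15),
                          bin_width = 0.05),
      o2v)
    vox <- maps$sparing$values[ph$o2$values == o2v][1]
    expect_equal(vox, f_scalar, tolerance = 1e-12)
  }
})

test_that("zero-dose voxels get sparing 1 and damage 0", {
  dv <- array(10, c(3, 3, 3))
  dv[1, 1, 1] <- 0
  maps <- voxel_sparing_map(voxel_grid(dv), voxel_grid(array(20, c(3, 3, 3))),
                            rate = 15)
  expect_equal(maps$sparing$values[1, 1, 1], 1)
  expect_equal(maps$damage$values[1, 1, 1], 0)
})

test_that("multi-pulse deliveries spare less per map than a single pulse", {
  dose <- voxel_grid(array(10, c(3, 3, 3)))
  o2 <- voxel_grid(array(20, c(3, 3, 3)))
  single <- voxel_sparing_map(dose, o2, rate = 15, count = 1)
  ten <- voxel_sparing_map(dose, o2, rate = 15, count = 10)
  expect_true(all(ten$sparing$values > single$sparing$values))
  # count pulses at dose/count, full re-oxygenation: matches the scalar value
  expect_equal(ten$sparing$values[1, 1, 1], sparing_factor_linear(20, 15, 1),
               tolerance = 1e-12)
})

test_that("effective dose is dose times sparing, bounded by physical dose", {
  ph <- gen_phantom(shape = c(8, 8, 8))
  maps <- voxel_sparing_map(ph$dose, ph$o2, rate = 15)
  eff <- effective_dose_map(ph$dose, maps$sparing)
  expect_true(all(eff$values <= ph$dose$values + 1e-12))
  expect_equal(eff$values, ph$dose$values * maps$sparing$values)
  ones <- voxel_grid(array(1, dim(ph$dose$values)), ph$dose$spacing)
  expect_equal(effective_dose_map(ph$dose, ones)$values, ph$dose$values)
})

test_that("mismatched grids raise a registration error", {
  a <- voxel_grid(array(1, c(3, 3, 3)))
  b <- voxel_grid(array(1, c(3, 3, 4)))
  expect_error(voxel_sparing_map(a, b, rate = 1),
               class = "flashodh_registration_error")
  c_ <- voxel_grid(array(1, c(3, 3, 3)), spacing = c(2, 2, 2))
  expect_error(effective_dose_map(a, c_),
               class = "flashodh_registration_error")
})

test_that("voxel summary reports the hypoxic dose fraction", {
  dose <- voxel_grid(array(15, c(4, 4, 4)))
  o2 <- voxel_grid(array(7, c(4, 4, 4)))
  maps <- voxel_sparing_map(dose, o2, rate = 0.6)
  s <- voxel_summary(dose, o2, maps$sparing, rate = 0.6, hypoxic_torr = 0)
  # 7 Torr at 0.6 Torr/Gy: hypoxia onset after 11.667 Gy of the 15 Gy
  expect_equal(s$hypoxic_dose_fraction, (15 - 7 / 0.6) / 15, tolerance = 1e-9)
  expect_equal(s$mean_sparing, sparing_factor_linear(7, 0.6, 15),
               tolerance = 1e-12)
  s0 <- voxel_summary(dose, o2, maps$sparing, rate = 0)
  expect_equal(s0$hypoxic_dose_fraction, 0)
})

test_that("voxel grids round-trip through NIfTI and long CSV", {
  ph <- gen_phantom(shape = c(5, 6, 7), noise_sd = 0.5, seed = 9)
  fn <- tempfile(fileext = ".nii.gz")
  write_voxel_nifti(ph$o2, fn)
  back <- read_voxel_nifti(fn)
  expect_equal(back$values, ph$o2$values, tolerance = 1e-6)
  expect_equal(back$spacing, ph$o2$spacing)

  fc <- tempfile(fileext = ".csv")
  write_voxel_csv(ph$dose, fc)
  back2 <- read_voxel_csv(fc, spacing = ph$dose$spacing)
  expect_equal(back2$values, ph$dose$values, tolerance = 1e-12)
})
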