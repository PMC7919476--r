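test_that("spectral constructors enforce their invariants", {
  expect_error(emission_spectrum(c(300, 300, 301), c(1, 2, 3)),
               "strictly increasing")
  expect_error(emission_spectrum(300:302, c(1, -2, 3)), "non-negative")
  expect_error(emission_spectrum(300:302, c(1, 2)), "same length")
  s <- gauss_spectrum(340)
  expect_error(titration_series("HSA", 2e-6, c(0, -1e-6), list(s, s), 298),
               "non-negative")
  expect_error(titration_series("HSA", 2e-6, c(2e-6, 1e-6), list(s, s), 298),
               "strictly increasing")
  expect_error(titration_series("HSA", 2e-6, c(0, 1e-6, 2e-6), list(s, s), 298),
               "does not match")
  s2 <- gauss_spectrum(340, grid = seq(310, 500, by = 1))
  expect_error(titration_series("HSA", 2e-6, c(0, 1e-6), list(s, s2), 298),
               "share one wavelength grid")
  expect_error(synchronous_series(-15, exact_titration(5e3)), "positive")
  expect_error(eem(c(220, 225), 250:260, matrix(0, 3, 11)), "dimensions")
  expect_error(absorption_spectrum(c(210, 205), c(0.1, 0.2)),
               "strictly increasing")
  expect_error(cd_spectrum(190:270, rep(-5, 81), 0, 585, 0.1), "> 0")
})

test_that("titration files round-trip bit-identically with their metadata", {
  # minimal 2-spectrum series
  tmp <- withr::local_tempfile(fileext = ".csv")
  small <- exact_titration(5e3, q = 2e-6)
  write_titration(small, tmp)
  back <- read_titration(tmp)
  expect_identical(back$quencher_conc_M, small$quencher_conc_M)
  expect_length(back$spectra, 2L)

  # full noisy generator output, truth in the header
  cfg <- generator_config(seed = 42, noise_pct = 1, K_A_ref = 6.22e4, n = 0.98)
  series <- simulate_titration(cfg, 298)
  truth <- attr(series, "truth")
  write_titration(series, tmp,
                  extra_meta = list(truth_K_A = truth$truth_K_A,
                                    truth_n = truth$truth_n))
  back <- read_titration(tmp)
  expect_identical(back$quencher_conc_M, series$quencher_conc_M)
  for (i in seq_along(series$spectra)) {
    expect_identical(back$spectra[[i]]$intensity, series$spectra[[i]]$intensity)
    expect_identical(back$spectra[[i]]$wavelength_nm,
                     series$spectra[[i]]$wavelength_nm)
  }
  expect_equal(attr(back, "truth")$truth_K_A, truth$truth_K_A)
  expect_identical(back$temperature_K, series$temperature_K)
})

test_that("a column/concentration mismatch is rejected at read time", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  series <- exact_titration(5e3, q = c(2e-6, 4e-6, 6e-6))
  write_titration(series, tmp)
  expect_error(
    read_titration(tmp, metadata = list(quencher_conc_M = c(0, 2e-6, 4e-6))),
    "4 intensity columns but metadata lists 3")
})

test_that("peak location recovers analytic Gaussian centres within 0.1 nm", {
  for (center in c(310.0, 325.37, 340.5, 343.0, 371.91, 489.2)) {
    pk <- peak_position(gauss_spectrum(center))
    expect_lt(abs(pk$peak_nm - center), 0.1)
    expect_false(pk$at_edge)
  }
  # non-uniform grid still uses the local three points
  grid <- sort(c(seq(300, 500, by = 2), 339.5, 340.5))
  y <- 1000 * exp(-(grid - 340.2)^2 / (2 * 25^2))
  pk <- peak_position(list(wavelength_nm = grid, intensity = y))
  expect_lt(abs(pk$peak_nm - 340.2), 0.1)
})

test_that("peak location flags edges and rejects flat spectra", {
  ramp <- list(wavelength_nm = 300:320, intensity = seq(1, 21))
  pk <- peak_position(ramp)
  expect_true(pk$at_edge)
  expect_identical(pk$peak_nm, 320)
  flat <- list(wavelength_nm = 300:320, intensity = rep(5, 21))
  expect_error(peak_position(flat), "indeterminate")
  expect_error(peak_position(ramp, window = c(200, 400)), "within the")
})

test_that("shift measurement classifies red/blue/none and is antisymmetric", {
  uv207 <- absorption_spectrum(200:350, exp(-((200:350) - 207)^2 / (2 * 7^2)))
  uv215 <- absorption_spectrum(200:350, exp(-((200:350) - 215)^2 / (2 * 7^2)))
  sh <- measure_shift(uv207, uv215)
  expect_equal(sh$shift_nm, 8, tolerance = 0.01)
  expect_identical(sh$direction, "red")

  em343 <- gauss_spectrum(343)
  em340 <- gauss_spectrum(340)
  sh <- measure_shift(em343, em340)
  expect_equal(sh$shift_nm, -3, tolerance = 0.01)
  expect_identical(sh$direction, "blue")

  same <- measure_shift(em343, em343)
  expect_equal(same$shift_nm, 0)
  expect_identical(same$direction, "none")

  # antisymmetry over assorted center pairs
  for (centers in list(c(340, 345), c(343, 340), c(320.5, 321.2))) {
    fwd <- measure_shift(gauss_spectrum(centers[1]), gauss_spectrum(centers[2]))
    rev <- measure_shift(gauss_spectrum(centers[2]), gauss_spectrum(centers[1]))
    expect_equal(fwd$shift_nm, -rev$shift_nm, tolerance = 1e-9)
  }
})

test_that("inner-filter correction is the documented multiplicative factor", {
  expect_identical(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * 10^0.1,
               tolerance = 1e-12)
  expect_equal(round(inner_filter_correct(100, 0.1, 0.1), 2), 125.89)
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
})
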