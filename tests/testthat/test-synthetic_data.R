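test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- generator_config(seed = 21, noise_pct = 2)
  a <- simulate_titration(cfg, 298)
  b <- simulate_titration(cfg, 298)
  for (i in seq_along(a$spectra)) {
    expect_identical(a$spectra[[i]]$intensity, b$spectra[[i]]$intensity)
  }
  expect_identical(simulate_eem(peaks = list(list(ex = 280, em = 340,
                                                  intensity = 1000)),
                                noise_pct = 1, seed = 3)$intensity,
                   simulate_eem(peaks = list(list(ex = 280, em = 340,
                                                  intensity = 1000)),
                                noise_pct = 1, seed = 3)$intensity)
  expect_identical(simulate_displacement(cfg, TRUE)$ratio,
                   simulate_displacement(cfg, TRUE)$ratio)
  expect_identical(simulate_cd(50, cfg)$ellipticity_mdeg,
                   simulate_cd(50, cfg)$ellipticity_mdeg)
})

test_that("the thermodynamic link sets K_A(T) exactly", {
  cfg <- generator_config(seed = 1, K_A_ref = NULL,
                          delta_H = -105.74, delta_S = -265.88)
  for (tk in cfg$temperatures_K) {
    expect_equal(truth_K_at(cfg, tk),
                 exp(-(-105.74) * 1000 / (R_GAS * tk) + (-265.88) / R_GAS),
                 tolerance = 1e-12)
  }
  # dynamic mode flips the trend: K rises with temperature
  dyn <- generator_config(seed = 1, K_A_ref = NULL, delta_H = -105.74,
                          delta_S = -265.88, mode = "dynamic")
  Ks <- vapply(dyn$temperatures_K, function(tk) truth_K_at(dyn, tk), numeric(1))
  expect_true(all(diff(Ks) > 0))
  # per-temperature explicit constants
  per_t <- generator_config(seed = 1, K_A_ref = c(6e4, 4e4, 2e4))
  expect_identical(truth_K_at(per_t, 303), 4e4)
})

test_that("at zero noise the titration generator inverts its analysis exactly", {
  cfg <- generator_config(seed = 2, K_A_ref = 6.22e4, n = 0.98)
  series <- simulate_titration(cfg, 298)
  # free-protein spectrum is the pure analytic band
  wl <- series$spectra[[1]]$wavelength_nm
  expect_equal(series$spectra[[1]]$intensity,
               1000 * exp(-(wl - 340)^2 / (2 * 25^2)), tolerance = 1e-12)
  b <- hill_fit(series)
  expect_lt(abs(b$K_A - 6.22e4) / 6.22e4, 1e-8)
  expect_lt(abs(b$n - 0.98), 1e-8)
  # truth attribute mirrors the config
  expect_identical(attr(series, "truth")$truth_K_A, 6.22e4)
})

test_that("enhancement mode raises the first two points before quenching", {
  cfg <- generator_config(seed = 3, K_A_ref = 5e5, n = 1,
                          mode = "enhancement_then_quench")
  series <- simulate_titration(cfg, 298)
  r <- quench_ratios(series)
  expect_true(all(r$ratio[2:3] < 1))        # F above F0: apparent enhancement
  expect_true(all(r$ratio[4:12] > 1))       # quenching resumes
  expect_equal(r$ratio[2], 1 / 1.05, tolerance = 1e-9)
})

test_that("two-site mode mixes the configured fast and slow components", {
  cfg2 <- generator_config(seed = 4, K_A_ref = 1e5, n = 1, mode = "two_site")
  series <- simulate_titration(cfg2, 298)
  r <- quench_ratios(series)
  q <- series$quencher_conc_M
  expected <- 1 / (0.7 / (1 + 1e5 * q) + 0.3 / (1 + 1e4 * q))
  expect_equal(r$ratio, expected, tolerance = 1e-9)
})

test_that("BSA settings move the band and residue count", {
  cfg <- generator_config(seed = 5, protein = "BSA")
  expect_identical(cfg$band_center_nm, 343)
  expect_identical(cfg$n_residues, 583)
  series <- simulate_titration(cfg, 298)
  expect_equal(peak_position(series$spectra[[1]])$peak_nm, 343,
               tolerance = 0.01)
})

test_that("generated files carry their ground truth in the header", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cfg <- generator_config(seed = 6, K_A_ref = 3.8e4, n = 0.9, noise_pct = 1)
  series <- simulate_titration(cfg, 303)
  truth <- attr(series, "truth")
  write_titration(series, tmp, extra_meta = truth[!vapply(truth, is.null,
                                                          logical(1))])
  back <- read_titration(tmp)
  expect_equal(attr(back, "truth")$truth_K_A, 3.8e4)
  expect_equal(attr(back, "truth")$truth_n, 0.9)
})
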