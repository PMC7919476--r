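test_that("mean residue ellipticity follows the 10 c n l normalisation", {
  zero <- cd_spectrum(190:270, rep(0, 81), 3e-6, 585, 0.1)
  expect_true(all(mre(zero)$mre == 0))
  one <- cd_spectrum(208, -10, 3e-6, 585, 0.1)
  expect_equal(mre(one)$mre, -10 / (10 * 3e-6 * 585 * 0.1), tolerance = 1e-12)
  expect_equal(round(mre(one)$mre), -5698)
  # linear in ellipticity, inverse in concentration
  two <- cd_spectrum(208, -20, 3e-6, 585, 0.1)
  expect_equal(mre(two)$mre, 2 * mre(one)$mre, tolerance = 1e-12)
  dbl_c <- cd_spectrum(208, -10, 6e-6, 585, 0.1)
  expect_equal(mre(dbl_c)$mre, mre(one)$mre / 2, tolerance = 1e-12)
})

test_that("alpha-helix content maps the 208 nm MRE onto its fixed scale", {
  expect_equal(as.numeric(alpha_helix_percent(-4000)), 0)
  expect_equal(as.numeric(alpha_helix_percent(-33000)), 100)
  expect_equal(as.numeric(alpha_helix_percent(-18592.8)), 50.32,
               tolerance = 1e-6)
  # algebraic inverse identity across the whole range
  for (alpha in seq(0, 100, by = 12.5)) {
    m208 <- -(alpha / 100 * 29000 + 4000)
    expect_equal(as.numeric(alpha_helix_percent(m208)), alpha,
                 tolerance = 1e-10)
  }
  # out-of-range values are clipped with the raw value retained
  expect_warning(high <- alpha_helix_percent(-40000), "clipped")
  expect_identical(as.numeric(high), 100)
  expect_gt(attr(high, "raw"), 100)
})

test_that("CD round trip recovers the generator's helix content", {
  cfg <- generator_config(seed = 4, protein = "HSA")
  for (alpha in c(0, 50.32, 57.20, 100)) {
    ss <- secondary_structure(simulate_cd(alpha, cfg))
    expect_equal(ss$alpha_helix_pct, alpha, tolerance = 1e-6)
  }
  # trivial anchors of the generator itself
  m <- mre(simulate_cd(0, cfg))
  expect_equal(mre_at(m, 208), -4000, tolerance = 1e-9)
  m <- mre(simulate_cd(100, cfg))
  expect_equal(mre_at(m, 208), -33000, tolerance = 1e-9)
})

test_that("synchronous scans report residue, quenching fraction and shift", {
  # 60 nm offset with a progressive 3 nm blue shift: tryptophan, blue
  cfg <- generator_config(seed = 5, shift_nm = -3)
  sa <- synchronous_analysis(simulate_synchronous(cfg, 60, final_quench = 0.4))
  expect_identical(sa$residue, "Trp")
  expect_identical(sa$shift$direction, "blue")
  expect_equal(sa$shift$shift_nm, -3, tolerance = 0.1)
  expect_lt(abs(sa$table$quench_fraction[nrow(sa$table)] - 0.40), 0.01)
  # both axis conventions are reported
  expect_equal(sa$table$peak_em_nm, sa$table$peak_ex_nm + 60)

  # 15 nm offset, no quenching at all: tyrosine, flat
  cfg0 <- generator_config(seed = 6, shift_nm = 0)
  sa0 <- synchronous_analysis(simulate_synchronous(cfg0, 15, final_quench = 0))
  expect_identical(sa0$residue, "Tyr")
  expect_identical(sa0$shift$direction, "none")
  expect_equal(sa0$table$quench_fraction, rep(0, nrow(sa0$table)),
               tolerance = 1e-9)
})

test_that("EEM peaks are recovered off the Rayleigh ridges", {
  e <- simulate_eem(peaks = list(list(ex = 280, em = 340, intensity = 1000),
                                 list(ex = 230, em = 330, intensity = 600)),
                    seed = 7)
  pk <- find_eem_peaks(e)
  expect_lt(abs(pk$peak1$excitation_nm - 280), 1)
  expect_lt(abs(pk$peak1$emission_nm - 340), 1)
  expect_lt(abs(pk$peak2$excitation_nm - 230), 1)
  expect_lt(abs(pk$peak2$emission_nm - 330), 1)
  expect_true(pk$rayleigh_1$present)
  expect_true(pk$rayleigh_2$present)
  # no fluorescence peak may sit inside a ridge tolerance band
  if (nrow(pk$all_peaks)) {
    expect_true(all(abs(pk$all_peaks$emission_nm - pk$all_peaks$excitation_nm) >
                      pk$ridge_tol_nm))
    expect_true(all(abs(pk$all_peaks$emission_nm -
                          2 * pk$all_peaks$excitation_nm) > pk$ridge_tol_nm))
  }
  # 1% noise keeps recovery within a nanometre
  en <- simulate_eem(peaks = list(list(ex = 280, em = 340, intensity = 1000)),
                     noise_pct = 1, seed = 8)
  pn <- find_eem_peaks(en)
  expect_lt(abs(pn$peak1$excitation_nm - 280), 1)
  expect_lt(abs(pn$peak1$emission_nm - 340), 1)
})

test_that("ridge-only and empty matrices yield no fluorescence peaks", {
  ridge_only <- simulate_eem(peaks = list(), ridges = TRUE, seed = 9)
  pk <- find_eem_peaks(ridge_only)
  expect_null(pk$peak1)
  expect_null(pk$peak2)
  zero <- eem(seq(220, 400, by = 5), seq(250, 500, by = 1),
              matrix(0, 37, 251))
  pz <- find_eem_peaks(zero)
  expect_identical(nrow(pz$all_peaks), 0L)
  expect_false(isTRUE(pz$rayleigh_1$present))
})

test_that("paired EEMs measure the imposed peak-intensity drop", {
  free <- simulate_eem(peaks = list(list(ex = 280, em = 340, intensity = 1000)),
                       noise_pct = 1, seed = 10)
  complexed <- simulate_eem(peaks = list(list(ex = 280, em = 340,
                                              intensity = 650)),
                            noise_pct = 1, seed = 11)
  expect_lt(abs(eem_peak_drop(free, complexed, "peak1") - 0.35), 0.02)
})

test_that("UV/Vis titrations track both absorption bands and their shifts", {
  cfg <- generator_config(seed = 12)
  uv <- simulate_uvvis(cfg, shift_peak1_nm = 8)
  res <- uvvis_analysis(uv$spectra, uv$quencher_conc_M)
  expect_equal(res$shift_peak1$shift_nm, 8, tolerance = 0.2)
  expect_identical(res$shift_peak1$direction, "red")
  expect_identical(res$shift_peak2$direction, "none")
  expect_equal(res$table$peak1_nm[1], 207, tolerance = 0.1)
  expect_equal(res$table$peak2_nm[1], 280, tolerance = 0.1)
  # absorbance falls with ligand addition
  expect_lt(res$table$peak1_abs[nrow(res$table)], res$table$peak1_abs[1])
  # a lone free-protein spectrum reports peaks but no shifts
  solo <- uvvis_analysis(uv$spectra[1], uv$quencher_conc_M[1])
  expect_null(solo$shift_peak1)
  expect_equal(solo$table$peak1_nm, 207, tolerance = 0.1)
})
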