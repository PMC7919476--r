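test_that("quenching ratios invert the generative static model exactly", {
  # identical spectra: no quenching anywhere
  s <- gauss_spectrum(340)
  flat_series <- titration_series("HSA", 2e-6, c(0, 2e-6, 4e-6),
                                  list(s, s, s), 298)
  r <- quench_ratios(flat_series)
  expect_equal(r$ratio, rep(1, 3))

  # F = F0 / (1 + K [Q]) gives back 1 + K [Q] to machine precision
  K <- 5e3
  series <- exact_titration(K)
  r <- quench_ratios(series)
  expect_equal(r$ratio, 1 + K * series$quencher_conc_M, tolerance = 1e-12)

  # both ratio policies agree when the band does not shift
  r2 <- quench_ratios(series, policy = "max")
  expect_equal(r2$ratio, r$ratio, tolerance = 1e-9)
})

test_that("a missing F0 source is an error", {
  s <- gauss_spectrum(340)
  no_zero <- titration_series("HSA", 2e-6, c(2e-6, 4e-6, 6e-6),
                              list(s, s, s), 298)
  expect_error(quench_ratios(no_zero), "no explicit F0")
  expect_silent(quench_ratios(no_zero, F0 = 1000))
})

test_that("the Stern-Volmer fit is exact on noise-free affine input", {
  q <- seq(2e-6, 32e-6, length.out = 11)
  for (K in c(5e3, 4.4e4, 2.1e5)) {
    r <- data.frame(quencher_conc_M = c(0, q), ratio = 1 + K * c(0, q))
    sv <- stern_volmer_fit(r, temperature_K = 298)
    expect_lt(abs(sv$K_SV - K) / K, 1e-10)
    expect_equal(sv$intercept, 1, tolerance = 1e-10)
    expect_equal(sv$r_squared, 1, tolerance = 1e-12)
  }
  # constant ratios: zero slope, undefined r2
  r <- data.frame(quencher_conc_M = c(0, q), ratio = rep(1, 12))
  sv <- stern_volmer_fit(r)
  expect_lt(abs(sv$K_SV), 1e-6)
  expect_true(is.na(sv$r_squared))
  expect_error(stern_volmer_fit(data.frame(quencher_conc_M = c(0, 1e-6),
                                           ratio = c(1, 1.1))),
               "at least 3")
})

test_that("K_q is K_SV over tau0 and scales inversely with the lifetime", {
  q <- seq(2e-6, 32e-6, length.out = 11)
  r <- data.frame(quencher_conc_M = q, ratio = 1 + 5000 * q)
  sv <- stern_volmer_fit(r, tau0_s = 1e-8)
  expect_equal(sv$K_q, 5e11, tolerance = 1e-9)
  expect_identical(sv$K_q, sv$K_SV / sv$tau0_s)
  sv2 <- stern_volmer_fit(r, tau0_s = 2e-8)
  expect_equal(sv2$K_q, sv$K_q / 2, tolerance = 1e-12)
})

test_that("enhancement points are excluded from the fit and recorded", {
  q <- seq(2e-6, 32e-6, length.out = 11)
  ratio <- 1 + 4e4 * q
  ratio[1:2] <- 0.95   # initial fluorescence rise
  r <- data.frame(quencher_conc_M = q, ratio = ratio)
  sv <- stern_volmer_fit(r)
  expect_identical(sv$excluded, 1:2)
  expect_lt(abs(sv$K_SV - 4e4) / 4e4, 1e-10)
})

test_that("the temperature trend of K_SV identifies the mechanism", {
  mk <- function(K, T) {
    q <- seq(2e-6, 32e-6, length.out = 11)
    stern_volmer_fit(data.frame(quencher_conc_M = q, ratio = 1 + K * q),
                     temperature_K = T)
  }
  temps <- c(298, 303, 310)
  falling <- Map(mk, c(6.0e4, 4.5e4, 3.0e4), temps)
  expect_identical(classify_mechanism(falling)$mechanism, "static")
  rising <- Map(mk, c(3.0e4, 4.5e4, 6.0e4), temps)
  expect_identical(classify_mechanism(rising)$mechanism, "dynamic")
  humped <- Map(mk, c(3.0e4, 6.0e4, 4.5e4), temps)
  call <- classify_mechanism(humped)
  expect_identical(call$mechanism, "indeterminate")
  expect_false(call$monotonic)
  expect_error(classify_mechanism(falling[1]), ">= 2 temperatures")
})

test_that("zero-noise studies across the study temperatures always classify static", {
  for (seed in 1:5) {
    cfg <- generator_config(seed = seed, K_A_ref = NULL, n = 0.98,
                            delta_H = -105.74, delta_S = -265.88)
    study <- simulate_study(cfg)
    svs <- lapply(study, function(s) stern_volmer_fit(quench_ratios(s)))
    expect_identical(classify_mechanism(svs)$mechanism, "static")
  }
})
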