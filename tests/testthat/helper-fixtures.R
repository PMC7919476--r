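# Shared in-code fixtures.

# Gaussian emission band sampled on a 1 nm grid.
gauss_spectrum <- function(center, sigma = 25, amplitude = 1000,
                           grid = seq(300, 500, by = 1), excitation = 295) {
  emission_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * sigma^2)),
                    excitation)
}

# Exact static-quenching titration built directly from the 1:1 binding
# model F = F0 / (1 + K [Q]^n), independent of the package's generator.
exact_titration <- function(K, n = 1, q = seq(2e-6, 32e-6, length.out = 11),
                            center = 340, temperature_K = 298) {
  qq <- c(0, q)
  spectra <- lapply(qq, function(qi) {
    s <- gauss_spectrum(center)
    emission_spectrum(s$wavelength_nm, s$intensity / (1 + K * qi^n),
                      s$excitation_nm)
  })
  titration_series("HSA", 2e-6, qq, spectra, temperature_K)
}

# Closed-form OLS slope/intercept (independent of stats::lm).
ols_line <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Per-complex thermodynamic truths from the published reference table.
ref_by_complex <- function() {
  ref <- reference_binding_params()
  split(ref, ref$complex)
}
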