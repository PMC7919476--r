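# Seeded generators for every input the pipeline consumes, with known
# ground truth: fluorescence titrations (static / dynamic / two-site /
# enhancement-then-quench modes), synchronous scans, site-marker
# displacement curves, CD spectra and excitation-emission matrices.
# For zero noise every generator is the exact algebraic inverse of its
# paired analysis operation.

#' Generator configuration
#'
#' Defines the study conditions a synthetic titration emulates: a fixed
#' 2e-6 mol/L serum albumin titrated with quencher from 2e-6 to 32e-6
#' mol/L (11 points; the free-protein spectrum is generated separately as
#' `[Q] = 0`) at 298/303/310 K. Ground truth is either per-temperature
#' association constants (`K_A_ref`) or a (`delta_H`, `delta_S`) pair from
#' which `K_A(T) = exp(-dH/(RT) + dS/R)` is derived exactly.
#'
#' @param seed Integer RNG seed.
#' @param protein `"HSA"` or `"BSA"`; sets residue count (585/583) and
#'   emission band centre (340/343 nm).
#' @param protein_conc_M Protein concentration, mol/L (default 2e-6).
#' @param quencher_concs_M Increasing non-zero quencher concentrations
#'   (default 11 points, 2e-6 to 32e-6 mol/L).
#' @param temperatures_K Study temperatures (default 298, 303, 310).
#' @param K_A_ref Association constant(s), L/mol: scalar, or one per
#'   temperature. Ignored when `delta_H`/`delta_S` are given.
#' @param n Binding-site number / Hill slope (default 1).
#' @param delta_H,delta_S Optional thermodynamic truth (kJ/mol and
#'   J/(mol K)) linking K_A across temperature via the van't Hoff
#'   relation.
#' @param band_center_nm Emission band centre; default 340 (HSA) or 343
#'   (BSA).
#' @param band_sigma_nm Gaussian band width (default 25).
#' @param band_amplitude Peak intensity of the free protein (default
#'   1000).
#' @param noise_pct Multiplicative Gaussian noise sigma, percent of signal
#'   (default 0).
#' @param shift_nm Progressive peak shift reached at the final titration
#'   point (signed; default 0).
#' @param mode `"static"`, `"dynamic"`, `"two_site"` or
#'   `"enhancement_then_quench"`.
#' @param excitation_nm Excitation wavelength (default 295).
#' @param wavelength_nm Emission grid (default 300-500 nm at 1 nm).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             protein = c("HSA", "BSA"),
                             protein_conc_M = 2e-6,
                             quencher_concs_M = seq(2e-6, 32e-6, length.out = 11),
                             temperatures_K = c(298, 303, 310),
                             K_A_ref = 6e4,
                             n = 1,
                             delta_H = NULL,
                             delta_S = NULL,
                             band_center_nm = NULL,
                             band_sigma_nm = 25,
                             band_amplitude = 1000,
                             noise_pct = 0,
                             shift_nm = 0,
                             mode = c("static", "dynamic", "two_site",
                                      "enhancement_then_quench"),
                             excitation_nm = 295,
                             wavelength_nm = seq(300, 500, by = 1)) {
  protein <- match.arg(protein)
  mode <- match.arg(mode)
  if (noise_pct < 0) stop("noise_pct must be >= 0", call. = FALSE)
  if (any(diff(quencher_concs_M) <= 0) || any(quencher_concs_M <= 0)) {
    stop("quencher_concs_M must be positive and strictly increasing",
         call. = FALSE)
  }
  if (is.null(band_center_nm)) {
    band_center_nm <- if (protein == "HSA") 340 else 343
  }
  if (!is.null(delta_H) != !is.null(delta_S)) {
    stop("delta_H and delta_S must be given together", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), protein = protein,
         n_residues = if (protein == "HSA") 585 else 583,
         protein_conc_M = protein_conc_M,
         quencher_concs_M = quencher_concs_M,
         temperatures_K = temperatures_K,
         K_A_ref = K_A_ref, n = n, delta_H = delta_H, delta_S = delta_S,
         band_center_nm = band_center_nm, band_sigma_nm = band_sigma_nm,
         band_amplitude = band_amplitude, noise_pct = noise_pct,
         shift_nm = shift_nm, mode = mode, excitation_nm = excitation_nm,
         wavelength_nm = wavelength_nm),
    class = "generator_config"
  )
}

#' Ground-truth association constant at a temperature
#'
#' When the config carries (`delta_H`, `delta_S`), returns
#' `exp(-dH * 1000 / (R T) + dS / R)` exactly; otherwise the configured
#' `K_A_ref` (scalar, or matched to `temperatures_K`). In `"dynamic"` mode
#' the enthalpy sign is flipped so the constant increases with temperature,
#' emulating collisional quenching for testing purposes.
#'
#' @param config A [generator_config].
#' @param temperature_K Temperature, K.
#' @return K_A in L/mol.
#' @export
truth_K_at <- function(config, temperature_K) {
  if (!is.null(config$delta_H)) {
    dH <- config$delta_H
    if (config$mode == "dynamic") dH <- -dH
    exp(-dH * 1000 / (R_GAS * temperature_K) + config$delta_S / R_GAS)
  } else if (length(config$K_A_ref) > 1L) {
    i <- match(temperature_K, config$temperatures_K)
    if (is.na(i)) stop("temperature not in config$temperatures_K", call. = FALSE)
    config$K_A_ref[i]
  } else {
    config$K_A_ref
  }
}

.gauss_band <- function(x, center, sigma, amplitude) {
  amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

#' Simulate a fluorescence quenching titration
#'
#' Generates a [titration_series] at one temperature by inverting the
#' static-quenching binding model: the free-protein spectrum is a Gaussian
#' emission band and each titration point is
#' `F(lambda, [Q]) = F0(lambda) / (1 + K_A [Q]^n)` with K_A from
#' [truth_K_at()]. Modes: `"static"` (default), `"dynamic"` (K rising with
#' temperature), `"two_site"` (mixture of two hyperbolic components:
#' 70% at K_A, 30% at K_A/10), `"enhancement_then_quench"` (a +5% intensity
#' rise at the two lowest concentrations, emulating an initial structural
#' opening before quenching sets in). Noise is multiplicative Gaussian;
#' `shift_nm` applies a linear progressive band shift over the titration.
#' Output is reproducible for a fixed seed; the truth parameters are
#' attached as the `"truth"` attribute.
#'
#' @param config A [generator_config].
#' @param temperature_K Temperature; default the config's first.
#' @return A [titration_series] with a leading `[Q] = 0` spectrum.
#' @export
simulate_titration <- function(config, temperature_K = config$temperatures_K[1]) {
  stopifnot(inherits(config, "generator_config"))
  ti <- match(temperature_K, config$temperatures_K)
  seed_off <- if (is.na(ti)) round(temperature_K) else ti
  set.seed(config$seed + seed_off)
  K <- truth_K_at(config, temperature_K)
  q <- c(0, config$quencher_concs_M)
  nq <- length(config$quencher_concs_M)
  wl <- config$wavelength_nm
  spectra <- lapply(seq_along(q), function(i) {
    frac_titr <- if (i == 1L) 0 else (i - 1) / nq
    center <- config$band_center_nm + config$shift_nm * frac_titr
    F0 <- .gauss_band(wl, center, config$band_sigma_nm, config$band_amplitude)
    quench <- switch(config$mode,
      static = ,
      dynamic = ,
      enhancement_then_quench = 1 / (1 + K * q[i]^config$n),
      two_site = 0.7 / (1 + K * q[i]^config$n) +
                 0.3 / (1 + (K / 10) * q[i]^config$n))
    f <- F0 * quench
    if (config$mode == "enhancement_then_quench" && i %in% c(2L, 3L)) {
      f <- F0 * 1.05   # initial rise overrides quenching at the 2 lowest [Q]
    }
    if (config$noise_pct > 0) {
      f <- f * (1 + stats::rnorm(length(f), sd = config$noise_pct / 100))
      f <- pmax(f, 0)
    }
    emission_spectrum(wl, f, config$excitation_nm)
  })
  out <- titration_series(config$protein, config$protein_conc_M, q, spectra,
                          temperature_K)
  attr(out, "truth") <- list(truth_K_A = K, truth_n = config$n,
                             truth_delta_H = config$delta_H,
                             truth_delta_S = config$delta_S,
                             truth_mode = config$mode,
                             truth_shift_nm = config$shift_nm,
                             truth_noise_pct = config$noise_pct)
  out
}

#' Simulate a full multi-temperature study
#'
#' One [simulate_titration()] per configured temperature.
#'
#' @param config A [generator_config].
#' @return Named list of [titration_series], names the temperatures.
#' @export
simulate_study <- function(config) {
  out <- lapply(config$temperatures_K, function(tk) simulate_titration(config, tk))
  names(out) <- as.character(config$temperatures_K)
  out
}

#' Simulate a synchronous scan series
#'
#' Same band model as [simulate_titration()] on an excitation-wavelength
#' axis (the synchronous peak sits `delta_lambda_nm` below the emission
#' band centre), with a configurable final quenching fraction and
#' progressive shift.
#'
#' @param config A [generator_config]; `shift_nm` and `noise_pct` apply.
#' @param delta_lambda_nm Scan offset, 15 (Tyr) or 60 (Trp).
#' @param final_quench Quenching fraction `1 - F/F0` reached at the highest
#'   concentration (default 0.4); intermediate points interpolate
#'   hyperbolically via an equivalent K.
#' @return A [synchronous_series] with truth attached.
#' @export
simulate_synchronous <- function(config, delta_lambda_nm = 60,
                                 final_quench = 0.4) {
  stopifnot(inherits(config, "generator_config"))
  if (final_quench < 0 || final_quench >= 1) {
    stop("final_quench must be in [0, 1)", call. = FALSE)
  }
  set.seed(config$seed + 1000L + round(delta_lambda_nm))
  q <- c(0, config$quencher_concs_M)
  qmax <- max(q)
  # equivalent 1:1 constant reaching the requested final quench fraction
  K_eq <- if (final_quench > 0) final_quench / ((1 - final_quench) * qmax) else 0
  center0 <- config$band_center_nm - delta_lambda_nm
  wl <- seq(200, 400, by = 1)
  nq <- length(config$quencher_concs_M)
  spectra <- lapply(seq_along(q), function(i) {
    frac_titr <- if (i == 1L) 0 else (i - 1) / nq
    center <- center0 + config$shift_nm * frac_titr
    f <- .gauss_band(wl, center, config$band_sigma_nm, config$band_amplitude) /
      (1 + K_eq * q[i])
    if (config$noise_pct > 0) {
      f <- pmax(f * (1 + stats::rnorm(length(f), sd = config$noise_pct / 100)), 0)
    }
    emission_spectrum(wl, f, NA_real_)
  })
  # synchronous scans are taken at room temperature
  series <- titration_series(config$protein, config$protein_conc_M, q, spectra,
                             298)
  out <- synchronous_series(delta_lambda_nm, series)
  attr(out, "truth") <- list(truth_final_quench = final_quench,
                             truth_shift_nm = config$shift_nm)
  out
}

#' Simulate a site-marker displacement curve
#'
#' `displaced = TRUE` yields ratios decaying to ~0.55 at the highest probe
#' concentration (well below the 0.8 displacement threshold);
#' `displaced = FALSE` keeps ratios within 1 +/- 0.05. Probe concentrations
#' default to the titration range.
#'
#' @param config A [generator_config] (seed, noise, concentrations).
#' @param displaced Logical: does this marker displace the ligand?
#' @param probe_id `"KPF"` or `"IBF"`.
#' @param probe_conc_M Probe concentrations; defaults to the config's
#'   titration range. All-zero concentrations yield all ratios 1.
#' @return A [displacement_curve].
#' @export
simulate_displacement <- function(config, displaced, probe_id = "KPF",
                                  probe_conc_M = config$quencher_concs_M) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2000L + as.integer(displaced) +
             10L * utf8ToInt(substr(probe_id, 1, 1)))
  q <- probe_conc_M
  if (all(q == 0)) return(displacement_curve(probe_id, q, rep(1, length(q))))
  frac <- q / max(q)
  ratio <- if (displaced) 1 - 0.45 * frac^0.9 else 1 - 0.02 * frac
  if (config$noise_pct > 0) {
    ratio <- ratio * (1 + stats::rnorm(length(ratio), sd = config$noise_pct / 100))
  }
  if (!displaced) ratio <- pmin(pmax(ratio, 0.95), 1.05)
  displacement_curve(probe_id, q, ratio)
}

#' Simulate a circular dichroism spectrum with known helix content
#'
#' Inverts the MRE/alpha-helix relations: sets
#' `MRE_208 = -(alpha_pct/100 * 29000 + 4000)`, renders the spectrum as two
#' negative Gaussian bands at 208 and 222 nm scaled to that value, and
#' converts to observed millidegrees with the config's concentration,
#' residue count and path length.
#'
#' @param alpha_pct Alpha-helix percentage in \[0, 100\].
#' @param config A [generator_config]; `protein_conc_M` defaults here to
#'   3e-6 mol/L CD conditions via `cd_conc_M`.
#' @param cd_conc_M Protein concentration for the CD sample (default
#'   3e-6 mol/L).
#' @param path_length_cm Cuvette path (default 0.1 cm).
#' @return A [cd_spectrum] with truth attached.
#' @export
simulate_cd <- function(alpha_pct, config, cd_conc_M = 3e-6,
                        path_length_cm = 0.1) {
  stopifnot(inherits(config, "generator_config"))
  if (alpha_pct < 0 || alpha_pct > 100) {
    stop("alpha_pct must be in [0, 100]", call. = FALSE)
  }
  set.seed(config$seed + 3000L)
  target_208 <- -(alpha_pct / 100 * 29000 + 4000)
  wl <- seq(190, 270, by = 1)
  shape <- -(exp(-(wl - 208)^2 / (2 * 9^2)) +
             0.95 * exp(-(wl - 222)^2 / (2 * 10^2)))
  shape_208 <- shape[wl == 208]
  mre_spec <- shape * (target_208 / shape_208)
  mdeg <- mre_spec * 10 * cd_conc_M * config$n_residues * path_length_cm
  if (config$noise_pct > 0) {
    mdeg <- mdeg * (1 + stats::rnorm(length(mdeg), sd = config$noise_pct / 100))
  }
  out <- cd_spectrum(wl, mdeg, cd_conc_M, config$n_residues, path_length_cm)
  attr(out, "truth") <- list(truth_alpha_pct = alpha_pct)
  out
}

#' Simulate an excitation-emission matrix
#'
#' Sum of 2-D Gaussian fluorescence peaks plus first- and second-order
#' Rayleigh ridge terms along `em = ex` and `em = 2 ex`, with optional
#' seeded multiplicative noise. Default grids follow a 220-400 nm
#' excitation scan in 5 nm steps and a 250-500 nm emission scan in 1 nm
#' steps.
#'
#' @param peaks List of peaks, each a list/vector with `ex`, `em`,
#'   `intensity` and optional `sigma_ex` (default 12), `sigma_em` (default
#'   15).
#' @param ridges Logical: add Rayleigh ridges (default `TRUE`).
#' @param ridge_intensity Ridge amplitude (default 300).
#' @param noise_pct Multiplicative noise sigma, percent (default 0).
#' @param seed RNG seed (default 1).
#' @param excitation_nm,emission_nm Grids.
#' @return An [eem] with truth attached.
#' @export
simulate_eem <- function(peaks = list(), ridges = TRUE, ridge_intensity = 300,
                         noise_pct = 0, seed = 1L,
                         excitation_nm = seq(220, 400, by = 5),
                         emission_nm = seq(250, 500, by = 1)) {
  if (length(peaks) == 0L && !ridges) {
    stop("need at least one peak or ridges enabled", call. = FALSE)
  }
  set.seed(seed)
  exg <- matrix(excitation_nm, nrow = length(excitation_nm),
                ncol = length(emission_nm))
  emg <- matrix(emission_nm, nrow = length(excitation_nm),
                ncol = length(emission_nm), byrow = TRUE)
  I <- matrix(0, nrow = length(excitation_nm), ncol = length(emission_nm))
  for (p in peaks) {
    p <- as.list(p)
    if (p$ex < min(excitation_nm) || p$ex > max(excitation_nm) ||
        p$em < min(emission_nm) || p$em > max(emission_nm)) {
      stop("peak outside the grid", call. = FALSE)
    }
    sx <- if (is.null(p$sigma_ex)) 12 else p$sigma_ex
    sy <- if (is.null(p$sigma_em)) 15 else p$sigma_em
    I <- I + p$intensity * exp(-(exg - p$ex)^2 / (2 * sx^2) -
                                 (emg - p$em)^2 / (2 * sy^2))
  }
  if (ridges) {
    I <- I + ridge_intensity * exp(-(emg - exg)^2 / (2 * 3^2)) +
      0.5 * ridge_intensity * exp(-(emg - 2 * exg)^2 / (2 * 4^2))
  }
  if (noise_pct > 0) {
    I <- pmax(I * (1 + stats::rnorm(length(I), sd = noise_pct / 100)), 0)
  }
  out <- eem(excitation_nm, emission_nm, I)
  attr(out, "truth") <- list(truth_peaks = peaks, truth_ridges = ridges)
  out
}

#' Simulate a UV/Vis absorption titration
#'
#' Two absorption bands (defaults: peak 1 at 207 nm, peak 2 at 280 nm)
#' whose intensities fall with ligand concentration; peak 1 optionally
#' drifts red by `shift_peak1_nm` over the titration while peak 2 stays
#' put.
#'
#' @param config A [generator_config].
#' @param shift_peak1_nm Total red shift of peak 1 at the final
#'   concentration (default 0).
#' @param drop_frac Fractional absorbance loss at the final concentration
#'   (default 0.3).
#' @return List with `spectra` (list of [absorption_spectrum]) and
#'   `quencher_conc_M` (including the leading 0), truth attached.
#' @export
simulate_uvvis <- function(config, shift_peak1_nm = 0, drop_frac = 0.3) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 4000L)
  q <- c(0, config$quencher_concs_M)
  nq <- length(config$quencher_concs_M)
  wl <- seq(200, 350, by = 1)
  spectra <- lapply(seq_along(q), function(i) {
    frac_titr <- if (i == 1L) 0 else (i - 1) / nq
    scale <- 1 - drop_frac * frac_titr
    a <- scale * (0.9 * exp(-(wl - (207 + shift_peak1_nm * frac_titr))^2 / (2 * 7^2)) +
                  0.35 * exp(-(wl - 280)^2 / (2 * 14^2)))
    if (config$noise_pct > 0) {
      a <- pmax(a * (1 + stats::rnorm(length(a), sd = config$noise_pct / 100)), 0)
    }
    absorption_spectrum(wl, a)
  })
  out <- list(spectra = spectra, quencher_conc_M = q)
  attr(out, "truth") <- list(truth_shift_peak1_nm = shift_peak1_nm,
                             truth_drop_frac = drop_frac)
  out
}
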