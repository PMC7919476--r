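#' Emission spectrum
#'
#' A single fluorescence emission spectrum: intensity on a strictly
#' increasing wavelength grid, recorded at a fixed excitation wavelength.
#'
#' @param wavelength_nm Numeric vector, strictly increasing wavelength grid
#'   in nm.
#' @param intensity Numeric vector of fluorescence intensities (arbitrary
#'   units), same length as `wavelength_nm`, non-negative.
#' @param excitation_nm Scalar excitation wavelength in nm.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm = NA_real_) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity)) {
    stop("wavelength_nm and intensity must have the same length", call. = FALSE)
  }
  if (length(wavelength_nm) < 1L || any(!is.finite(wavelength_nm))) {
    stop("wavelength grid must be finite and non-empty", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensity must be non-negative", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, intensity = intensity,
         excitation_nm = as.numeric(excitation_nm)[1]),
    class = "emission_spectrum"
  )
}

#' Fluorescence titration series
#'
#' Emission spectra of a protein at fixed concentration titrated with
#' increasing quencher concentrations at one temperature. Houses the F0
#' (free protein), F (quenched) and \[Q\] quantities of the Stern-Volmer
#' and double-logarithm analyses.
#'
#' @param protein_id Label, e.g. `"HSA"` or `"BSA"`.
#' @param protein_conc_M Protein concentration in mol/L.
#' @param quencher_conc_M Non-negative, strictly increasing quencher
#'   concentrations in mol/L; a leading 0 denotes the free-protein spectrum.
#' @param spectra List of [emission_spectrum] objects, one per
#'   concentration, all sharing one wavelength grid.
#' @param temperature_K Scalar temperature in kelvin.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(protein_id, protein_conc_M, quencher_conc_M,
                             spectra, temperature_K) {
  quencher_conc_M <- as.numeric(quencher_conc_M)
  if (any(quencher_conc_M < 0)) {
    stop("quencher concentrations must be non-negative", call. = FALSE)
  }
  if (length(quencher_conc_M) > 1L && any(diff(quencher_conc_M) <= 0)) {
    stop("quencher concentrations must be strictly increasing", call. = FALSE)
  }
  if (length(spectra) != length(quencher_conc_M)) {
    stop(sprintf(
      "number of spectra (%d) does not match number of quencher concentrations (%d)",
      length(spectra), length(quencher_conc_M)), call. = FALSE)
  }
  if (!all(vapply(spectra, inherits, logical(1), "emission_spectrum"))) {
    stop("spectra must be a list of emission_spectrum objects", call. = FALSE)
  }
  grid <- spectra[[1]]$wavelength_nm
  same <- vapply(spectra, function(s) identical(s$wavelength_nm, grid), logical(1))
  if (!all(same)) {
    stop("all spectra in a titration series must share one wavelength grid",
         call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id)[1],
         protein_conc_M = as.numeric(protein_conc_M)[1],
         quencher_conc_M = quencher_conc_M,
         spectra = spectra,
         temperature_K = as.numeric(temperature_K)[1]),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %s, %g mol/L protein, %d spectra, [Q] %g-%g mol/L, %g K\n",
    x$protein_id, x$protein_conc_M, length(x$spectra),
    min(x$quencher_conc_M), max(x$quencher_conc_M), x$temperature_K))
  invisible(x)
}

#' Synchronous fluorescence scan series
#'
#' A titration series scanned synchronously with a constant
#' excitation-emission offset. The x-axis of the member spectra is the
#' scanned excitation wavelength; the emitting wavelength is
#' `x + delta_lambda_nm`. Offsets of 15 nm and 60 nm isolate tyrosine and
#' tryptophan environments respectively.
#'
#' @param delta_lambda_nm Positive scan offset in nm (15 or 60 for residue
#'   attribution; other values are accepted but unattributed).
#' @param series A [titration_series] whose spectra's x-axis is excitation
#'   wavelength.
#' @return An object of class `synchronous_series`.
#' @export
synchronous_series <- function(delta_lambda_nm, series) {
  delta_lambda_nm <- as.numeric(delta_lambda_nm)[1]
  if (!is.finite(delta_lambda_nm) || delta_lambda_nm <= 0) {
    stop("delta_lambda_nm must be positive", call. = FALSE)
  }
  stopifnot(inherits(series, "titration_series"))
  structure(list(delta_lambda_nm = delta_lambda_nm, series = series),
            class = "synchronous_series")
}

#' Excitation-emission matrix
#'
#' @param excitation_nm Strictly increasing excitation grid (nm).
#' @param emission_nm Strictly increasing emission grid (nm).
#' @param intensity Matrix of intensities, `length(excitation_nm)` rows by
#'   `length(emission_nm)` columns.
#' @return An object of class `eem`.
#' @export
eem <- function(excitation_nm, emission_nm, intensity) {
  excitation_nm <- as.numeric(excitation_nm)
  emission_nm <- as.numeric(emission_nm)
  intensity <- as.matrix(intensity)
  if (any(diff(excitation_nm) <= 0) || any(diff(emission_nm) <= 0)) {
    stop("excitation and emission grids must be strictly increasing",
         call. = FALSE)
  }
  if (nrow(intensity) != length(excitation_nm) ||
      ncol(intensity) != length(emission_nm)) {
    stop("intensity matrix dimensions must match the excitation/emission grids",
         call. = FALSE)
  }
  structure(list(excitation_nm = excitation_nm, emission_nm = emission_nm,
                 intensity = intensity), class = "eem")
}

#' UV/Vis absorption spectrum
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param absorbance Dimensionless absorbance values (AU).
#' @return An object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(wavelength_nm, absorbance) {
  wavelength_nm <- as.numeric(wavelength_nm)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength_nm) != length(absorbance)) {
    stop("wavelength_nm and absorbance must have the same length", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelength_nm = wavelength_nm, absorbance = absorbance),
            class = "absorption_spectrum")
}

#' Circular dichroism spectrum
#'
#' Observed ellipticity in millidegrees together with the parameters needed
#' to convert to mean residue ellipticity: protein concentration `c`
#' (mol/L), residue count `n` (585 for HSA, 583 for BSA) and path length
#' `l` (cm).
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param ellipticity_mdeg Observed CD signal in millidegrees.
#' @param protein_conc_M Protein concentration in mol/L (> 0).
#' @param n_residues Number of amino-acid residues (> 0).
#' @param path_length_cm Cuvette path length in cm (> 0).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength_nm, ellipticity_mdeg, protein_conc_M,
                        n_residues, path_length_cm) {
  wavelength_nm <- as.numeric(wavelength_nm)
  ellipticity_mdeg <- as.numeric(ellipticity_mdeg)
  if (length(wavelength_nm) != length(ellipticity_mdeg)) {
    stop("wavelength_nm and ellipticity_mdeg must have the same length",
         call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (!isTRUE(protein_conc_M > 0)) stop("protein_conc_M must be > 0", call. = FALSE)
  if (!isTRUE(n_residues > 0)) stop("n_residues must be > 0", call. = FALSE)
  if (!isTRUE(path_length_cm > 0)) stop("path_length_cm must be > 0", call. = FALSE)
  structure(
    list(wavelength_nm = wavelength_nm, ellipticity_mdeg = ellipticity_mdeg,
         protein_conc_M = as.numeric(protein_conc_M),
         n_residues = as.numeric(n_residues),
         path_length_cm = as.numeric(path_length_cm)),
    class = "cd_spectrum"
  )
}
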