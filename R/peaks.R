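# Peak location, shift measurement and small spectral utilities shared by
# every downstream stage.

.spectrum_xy <- function(spectrum) {
  if (inherits(spectrum, "emission_spectrum")) {
    list(x = spectrum$wavelength_nm, y = spectrum$intensity)
  } else if (inherits(spectrum, "absorption_spectrum")) {
    list(x = spectrum$wavelength_nm, y = spectrum$absorbance)
  } else if (is.list(spectrum) && !is.null(spectrum$wavelength_nm)) {
    y <- if (!is.null(spectrum$intensity)) spectrum$intensity else spectrum$absorbance
    list(x = as.numeric(spectrum$wavelength_nm), y = as.numeric(y))
  } else if (is.data.frame(spectrum) && ncol(spectrum) >= 2) {
    list(x = as.numeric(spectrum[[1]]), y = as.numeric(spectrum[[2]]))
  } else {
    stop("unsupported spectrum object", call. = FALSE)
  }
}

# Vertex of the quadratic through three (x, y) points; works on non-uniform
# grids. Returns NA when the points are not concave.
.parabolic_vertex <- function(x, y) {
  d <- cbind(1, x, x^2)
  co <- tryCatch(solve(d, y), error = function(e) rep(NA_real_, 3))
  if (!all(is.finite(co)) || co[3] >= 0) return(NA_real_)
  unname(-co[2] / (2 * co[3]))
}

#' Locate a spectral peak
#'
#' Finds the maximum of a spectrum inside a wavelength window and refines
#' its position by parabolic interpolation through the discrete maximum and
#' its two neighbours. At a grid edge no interpolation is possible and the
#' discrete maximum is returned with `at_edge = TRUE`.
#'
#' @param spectrum An [emission_spectrum], [absorption_spectrum], or any
#'   two-column wavelength/intensity object.
#' @param window Optional `c(min_nm, max_nm)` search window; defaults to the
#'   whole grid. Must lie within the grid span.
#' @return A list with `peak_nm` (interpolated position, 0.1 nm reporting
#'   resolution retained in full precision), `peak_intensity` (value at the
#'   discrete maximum) and `at_edge`.
#' @export
peak_position <- function(spectrum, window = NULL) {
  xy <- .spectrum_xy(spectrum)
  x <- xy$x; y <- xy$y
  if (!is.null(window)) {
    if (window[1] < min(x) || window[2] > max(x)) {
      stop("window must lie within the wavelength grid span", call. = FALSE)
    }
    keep <- x >= window[1] & x <= window[2]
    if (!any(keep)) stop("empty peak search window", call. = FALSE)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) == 0L) stop("empty peak search window", call. = FALSE)
  if (diff(range(y)) == 0) {
    stop("peak position indeterminate: all intensities equal", call. = FALSE)
  }
  i <- which.max(y)
  at_edge <- i == 1L || i == length(x)
  peak_nm <- x[i]
  if (!at_edge) {
    v <- .parabolic_vertex(x[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
    # keep the refinement only if it stays between the neighbouring points
    if (is.finite(v) && v >= x[i - 1] && v <= x[i + 1]) peak_nm <- v
  }
  list(peak_nm = peak_nm, peak_intensity = y[i], at_edge = at_edge)
}

#' Measure a peak shift between two spectra
#'
#' Locates the peak of a reference and an observed spectrum over a shared
#' window and classifies the signed shift (observed minus reference):
#' shifts smaller in magnitude than `threshold_nm` count as `"none"`,
#' negative shifts as `"blue"` (towards shorter wavelength), positive as
#' `"red"`.
#'
#' @param reference,observed Spectra accepted by [peak_position()].
#' @param threshold_nm Classification threshold in nm (default 2: sub-2 nm
#'   movements are treated as unchanged).
#' @param window Optional shared search window.
#' @return An object of class `peak_shift` with fields `reference_peak_nm`,
#'   `observed_peak_nm`, `shift_nm` and `direction`.
#' @export
measure_shift <- function(reference, observed, threshold_nm = 2, window = NULL) {
  ref <- peak_position(reference, window)
  obs <- peak_position(observed, window)
  shift <- obs$peak_nm - ref$peak_nm
  direction <- if (abs(shift) < threshold_nm) "none" else if (shift < 0) "blue" else "red"
  structure(
    list(reference_peak_nm = ref$peak_nm, observed_peak_nm = obs$peak_nm,
         shift_nm = shift, direction = direction, threshold_nm = threshold_nm),
    class = "peak_shift"
  )
}

#' @export
print.peak_shift <- function(x, ...) {
  cat(sprintf("<peak_shift> %.1f -> %.1f nm (%+.1f nm, %s)\n",
              x$reference_peak_nm, x$observed_peak_nm, x$shift_nm, x$direction))
  invisible(x)
}

#' Inner-filter correction
#'
#' Multiplicative correction of observed fluorescence for attenuation of the
#' excitation and emission beams by sample absorbance:
#' `F_corr = F_obs * 10^((A_ex + A_em) / 2)`. With both absorbances zero the
#' correction is the identity. Provided as an optional utility; at the low
#' protein concentrations the analyses assume (absorbance < 0.1), the
#' correction is small.
#'
#' @param F_obs Observed fluorescence intensity (vectorised).
#' @param A_ex Absorbance at the excitation wavelength (>= 0).
#' @param A_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected fluorescence, same shape as `F_obs`.
#' @export
inner_filter_correct <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  F_obs * 10^((A_ex + A_em) / 2)
}

#' Optional Savitzky-Golay smoothing
#'
#' Off by default everywhere in the pipeline: intensities are analysed
#' as-is. Exposed for noisy instrument data.
#'
#' @param spectrum An [emission_spectrum] or [absorption_spectrum].
#' @param p Polynomial order (default 3).
#' @param n Window length, odd (default 11).
#' @return The spectrum with smoothed intensities.
#' @export
smooth_spectrum <- function(spectrum, p = 3, n = 11) {
  xy <- .spectrum_xy(spectrum)
  sm <- signal::sgolayfilt(xy$y, p = p, n = n)
  if (inherits(spectrum, "absorption_spectrum")) {
    absorption_spectrum(xy$x, sm)
  } else {
    emission_spectrum(xy$x, pmax(sm, 0), spectrum$excitation_nm)
  }
}

# Intensity at a wavelength, estimated from a quadratic fit of the
# log-intensity over a local window: exact for a Gaussian band (whose log
# is a parabola) and robust to single-point noise. Falls back to linear
# interpolation when the window holds too few positive points or the fit
# half-width is 0.
.band_intensity_at <- function(spectrum, wavelength_nm, halfwidth_nm = 12) {
  xy <- .spectrum_xy(spectrum)
  keep <- abs(xy$x - wavelength_nm) <= halfwidth_nm & xy$y > 0
  if (halfwidth_nm <= 0 || sum(keep) < 5L) {
    return(.intensity_at(spectrum, wavelength_nm))
  }
  xc <- xy$x[keep] - wavelength_nm
  fit <- stats::lm(log(xy$y[keep]) ~ xc + I(xc^2))
  exp(unname(stats::coef(fit)[1]))
}

# Intensity at (or linearly interpolated to) a wavelength.
.intensity_at <- function(spectrum, wavelength_nm) {
  xy <- .spectrum_xy(spectrum)
  if (wavelength_nm < min(xy$x) || wavelength_nm > max(xy$x)) {
    stop("wavelength outside the grid span", call. = FALSE)
  }
  stats::approx(xy$x, xy$y, xout = wavelength_nm)$y
}
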