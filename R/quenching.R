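# Stern-Volmer analysis: F0/F = 1 + K_SV [Q] = 1 + K_q tau0 [Q].
# The quenching mechanism is read off the temperature trend of K_SV:
# complex-driven (static) quenching weakens on heating, collisional
# (dynamic) quenching strengthens.

#' Quenching ratios F0/F from a titration series
#'
#' Computes the Stern-Volmer ratio F0/F at each quencher concentration.
#' Under the default `"fixed"` policy, F is read at the emission peak of
#' the free-protein spectrum for every spectrum in the series — robust to
#' small peak shifts during titration. Under `"max"`, each spectrum's own
#' peak intensity is used.
#'
#' @param series A [titration_series] containing a `[Q] = 0` spectrum, or
#'   an explicit `F0`.
#' @param policy `"fixed"` (intensity at the free-protein peak wavelength)
#'   or `"max"` (per-spectrum maximum).
#' @param F0 Optional explicit free-protein intensity, required when the
#'   series has no zero-concentration spectrum.
#' @param fit_halfwidth_nm Half-width of the local band-fit window used to
#'   read intensities at the reference wavelength (default 12 nm). The
#'   reading is the value at the reference wavelength of a quadratic fit
#'   to the log-intensity over this window — exact for a Gaussian band and
#'   insensitive to single-point noise, which a raw one-point reading
#'   would propagate (amplified) into the downstream double-log intercept.
#'   Set to 0 to read single raw (linearly interpolated) points.
#' @return A data frame with columns `quencher_conc_M`, `F`, `ratio`
#'   (= F0/F); attributes `F0` and `ref_wavelength_nm` record the
#'   reference used.
#' @export
quench_ratios <- function(series, policy = c("fixed", "max"), F0 = NULL,
                          fit_halfwidth_nm = 12) {
  policy <- match.arg(policy)
  stopifnot(inherits(series, "titration_series"))
  i0 <- which(series$quencher_conc_M == 0)
  if (length(i0) == 0L && is.null(F0)) {
    stop("series has no [Q] = 0 spectrum and no explicit F0 was given",
         call. = FALSE)
  }
  ref_spec <- series$spectra[[if (length(i0)) i0[1] else 1L]]
  ref_wl <- peak_position(ref_spec)$peak_nm
  f_at <- function(s) {
    if (policy == "max") return(peak_position(s)$peak_intensity)
    .band_intensity_at(s, ref_wl, fit_halfwidth_nm)
  }
  Fvals <- vapply(series$spectra, f_at, numeric(1))
  if (is.null(F0)) F0 <- Fvals[i0[1]]
  if (any(Fvals <= 0)) stop("non-positive fluorescence intensity", call. = FALSE)
  if (F0 <= 0) stop("non-positive F0", call. = FALSE)
  out <- data.frame(quencher_conc_M = series$quencher_conc_M, F = Fvals,
                    ratio = F0 / Fvals)
  if (length(i0)) out$ratio[i0[1]] <- 1
  attr(out, "F0") <- F0
  attr(out, "ref_wavelength_nm") <- ref_wl
  attr(out, "temperature_K") <- series$temperature_K
  out
}

#' Stern-Volmer result
#'
#' @param ratios Data frame from [quench_ratios()], or any data frame with
#'   `quencher_conc_M` and `ratio` columns.
#' @param tau0_s Fluorophore lifetime without quencher, in seconds. Default
#'   `1e-8` s, the conventional average biopolymer fluorescence lifetime;
#'   always echoed in the result.
#' @param temperature_K Temperature; taken from the `ratios` attribute when
#'   absent.
#' @param exclude_enhanced Drop points with F0/F < 1 (fluorescence
#'   enhancement, incompatible with pure quenching) from the fit; they are
#'   recorded in the `excluded` field. Default `TRUE`.
#' @return An object of class `sv_result`: `K_SV` (L/mol), `intercept`,
#'   `r_squared`, `temperature_K`, `K_q` (= K_SV / tau0, L/(mol s)),
#'   `tau0_s`, `excluded` (row indices dropped from the fit).
#' @details The fit is unweighted ordinary least squares of F0/F on \[Q\];
#'   at least 3 points must remain after exclusion. For exactly constant
#'   ratios the slope is 0 and `r_squared` is `NA` (undefined).
#' @export
stern_volmer_fit <- function(ratios, tau0_s = 1e-8, temperature_K = NULL,
                             exclude_enhanced = TRUE) {
  q <- ratios$quencher_conc_M
  r <- ratios$ratio
  if (is.null(temperature_K)) temperature_K <- attr(ratios, "temperature_K")
  if (any(!is.finite(q)) || any(!is.finite(r))) {
    stop("non-finite Stern-Volmer input", call. = FALSE)
  }
  excluded <- integer(0)
  if (exclude_enhanced) {
    excluded <- which(r < 1 & q > 0)
    if (length(excluded)) {
      q <- q[-excluded]; r <- r[-excluded]
    }
  }
  if (length(q) < 3L) {
    stop("Stern-Volmer fit needs at least 3 concentration points", call. = FALSE)
  }
  fit <- stats::lm(r ~ q)
  r2 <- if (stats::var(r) == 0) NA_real_ else suppressWarnings(summary(fit)$r.squared)
  K_SV <- unname(stats::coef(fit)[2])
  structure(
    list(K_SV = K_SV, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         temperature_K = if (is.null(temperature_K)) NA_real_ else temperature_K,
         K_q = K_SV / tau0_s, tau0_s = tau0_s, excluded = excluded),
    class = "sv_result"
  )
}

#' @export
print.sv_result <- function(x, ...) {
  cat(sprintf(
    "<sv_result> T = %g K: K_SV = %.4g L/mol, K_q = %.4g L/(mol s) (tau0 = %g s), r2 = %.5f\n",
    x$temperature_K, x$K_SV, x$K_q, x$tau0_s,
    if (is.na(x$r_squared)) NA else x$r_squared))
  invisible(x)
}

#' Classify the quenching mechanism from the temperature trend
#'
#' Static (ground-state complex) quenching constants fall with rising
#' temperature as the complex destabilises; dynamic (collisional) constants
#' rise with temperature through faster diffusion. A strictly decreasing
#' K_SV across temperatures is therefore called `"static"`, strictly
#' increasing `"dynamic"`, anything else `"indeterminate"`.
#'
#' @param sv_results List of [stern_volmer_fit()] results at two or more
#'   distinct temperatures.
#' @return An object of class `mechanism_call` with fields `mechanism`,
#'   `evidence` (data frame of temperature and K_SV, sorted by
#'   temperature) and `monotonic`.
#' @export
classify_mechanism <- function(sv_results) {
  if (inherits(sv_results, "sv_result")) sv_results <- list(sv_results)
  if (length(sv_results) < 2L) {
    stop("mechanism classification needs results at >= 2 temperatures",
         call. = FALSE)
  }
  ev <- data.frame(
    temperature_K = vapply(sv_results, `[[`, numeric(1), "temperature_K"),
    K_SV = vapply(sv_results, `[[`, numeric(1), "K_SV"))
  if (anyDuplicated(ev$temperature_K)) {
    stop("duplicate temperatures in mechanism classification", call. = FALSE)
  }
  ev <- ev[order(ev$temperature_K), , drop = FALSE]
  d <- diff(ev$K_SV)
  mechanism <- if (all(d < 0)) "static" else if (all(d > 0)) "dynamic" else "indeterminate"
  structure(
    list(mechanism = mechanism, evidence = ev,
         monotonic = all(d < 0) || all(d > 0)),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (K_SV: %s over T: %s)\n", x$mechanism,
              paste(signif(x$evidence$K_SV, 4), collapse = " > "),
              paste(x$evidence$temperature_K, collapse = ", ")))
  invisible(x)
}
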