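# Structural spectroscopy: synchronous-scan quenching and shifts, 3D
# excitation-emission peak characterisation (with Rayleigh scattering
# ridges masked), UV/Vis peak-shift analysis, and circular dichroism ->
# mean residue ellipticity -> alpha-helix content.

#' Mean residue ellipticity spectrum
#'
#' `MRE(lambda) = ellipticity_mdeg(lambda) / (10 c n l)` with `c` the molar
#' protein concentration, `n` the residue count and `l` the path length in
#' cm; units deg cm^2/dmol.
#'
#' @param cd A [cd_spectrum].
#' @return Data frame with columns `wavelength_nm` and `mre`.
#' @export
mre <- function(cd) {
  stopifnot(inherits(cd, "cd_spectrum"))
  denom <- 10 * cd$protein_conc_M * cd$n_residues * cd$path_length_cm
  data.frame(wavelength_nm = cd$wavelength_nm, mre = cd$ellipticity_mdeg / denom)
}

#' MRE value at a wavelength
#'
#' Linear interpolation on the MRE spectrum (exact when the wavelength is a
#' grid point).
#'
#' @param mre_spectrum Data frame from [mre()].
#' @param wavelength_nm Query wavelength (default 208, the alpha-helix
#'   quantification band).
#' @return MRE in deg cm^2/dmol.
#' @export
mre_at <- function(mre_spectrum, wavelength_nm = 208) {
  stats::approx(mre_spectrum$wavelength_nm, mre_spectrum$mre,
                xout = wavelength_nm)$y
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' `alpha(%) = (-MRE_208 - 4000) / (33000 - 4000) * 100`. Values outside
#' \[0, 100\] are clipped with a warning; the raw value is kept in the
#' `"raw"` attribute.
#'
#' @param mre_208 MRE at 208 nm, deg cm^2/dmol (finite).
#' @return Alpha-helix percentage (clipped to \[0, 100\]), with attribute
#'   `raw` holding the unclipped value.
#' @export
alpha_helix_percent <- function(mre_208) {
  if (!is.finite(mre_208)) stop("MRE at 208 nm must be finite", call. = FALSE)
  raw <- (-mre_208 - 4000) / (33000 - 4000) * 100
  out <- raw
  if (raw < 0 || raw > 100) {
    warning(sprintf("alpha-helix estimate %.2f%% outside [0, 100]; clipped", raw))
    out <- min(max(raw, 0), 100)
  }
  attr(out, "raw") <- raw
  out
}

#' Secondary-structure summary from a CD spectrum
#'
#' Chains [mre()], [mre_at()] at 208 nm and [alpha_helix_percent()]. The
#' 222 nm band value is reported for characterisation but not used for a
#' second helix estimate.
#'
#' @param cd A [cd_spectrum].
#' @return An object of class `secondary_structure`: `alpha_helix_pct`,
#'   `alpha_helix_raw`, `mre_208`, `mre_222`.
#' @export
secondary_structure <- function(cd) {
  m <- mre(cd)
  m208 <- mre_at(m, 208)
  pct <- alpha_helix_percent(m208)
  structure(
    list(alpha_helix_pct = as.numeric(pct),
         alpha_helix_raw = attr(pct, "raw"),
         mre_208 = m208,
         mre_222 = mre_at(m, 222)),
    class = "secondary_structure"
  )
}

#' Synchronous-scan quenching and shift analysis
#'
#' For each quencher concentration, locates the synchronous peak and the
#' quenching fraction `1 - F/F0` (F read at the free-protein peak
#' position), and measures the peak shift of the highest-concentration scan
#' against the free protein. A 15 nm offset is attributed to tyrosine, a
#' 60 nm offset to tryptophan; other offsets are left unattributed. The
#' x-axis is the scanned excitation wavelength; peaks are reported in both
#' conventions (`peak_ex_nm` and `peak_em_nm = peak_ex_nm + delta_lambda`).
#'
#' @param sync A [synchronous_series].
#' @param threshold_nm Shift classification threshold (default 2).
#' @return An object of class `synchronous_result`: `residue`,
#'   `delta_lambda_nm`, `table` (per-concentration peaks and quenching
#'   fractions) and `shift` (a `peak_shift`).
#' @export
synchronous_analysis <- function(sync, threshold_nm = 2) {
  stopifnot(inherits(sync, "synchronous_series"))
  series <- sync$series
  residue <- if (sync$delta_lambda_nm == 15) "Tyr"
             else if (sync$delta_lambda_nm == 60) "Trp"
             else NA_character_
  i0 <- which(series$quencher_conc_M == 0)
  if (length(i0) == 0L) {
    stop("synchronous analysis needs a free-protein ([Q] = 0) scan", call. = FALSE)
  }
  free <- series$spectra[[i0[1]]]
  ref <- peak_position(free)
  F0 <- ref$peak_intensity
  tab <- do.call(rbind, lapply(seq_along(series$spectra), function(i) {
    s <- series$spectra[[i]]
    pk <- peak_position(s)
    data.frame(quencher_conc_M = series$quencher_conc_M[i],
               peak_ex_nm = pk$peak_nm,
               peak_em_nm = pk$peak_nm + sync$delta_lambda_nm,
               peak_intensity = pk$peak_intensity,
               quench_fraction = 1 - .intensity_at(s, ref$peak_nm) / F0)
  }))
  shift <- measure_shift(free, series$spectra[[length(series$spectra)]],
                         threshold_nm = threshold_nm)
  structure(
    list(residue = residue, delta_lambda_nm = sync$delta_lambda_nm,
         table = tab, shift = shift),
    class = "synchronous_result"
  )
}

# --- excitation-emission matrices -------------------------------------------

.ridge_masks <- function(x, tol) {
  exg <- matrix(x$excitation_nm, nrow = length(x$excitation_nm),
                ncol = length(x$emission_nm))
  emg <- matrix(x$emission_nm, nrow = length(x$excitation_nm),
                ncol = length(x$emission_nm), byrow = TRUE)
  list(r1 = abs(emg - exg) <= tol, r2 = abs(emg - 2 * exg) <= tol)
}

.ridge_summary <- function(x, mask) {
  if (!any(mask)) {
    return(list(present = FALSE, max_intensity = NA_real_,
                excitation_nm = NA_real_, emission_nm = NA_real_))
  }
  v <- x$intensity[mask]
  mx <- max(v)
  idx <- which(x$intensity == mx & mask, arr.ind = TRUE)[1, ]
  list(present = mx > 0, max_intensity = mx,
       excitation_nm = x$excitation_nm[idx[1]],
       emission_nm = x$emission_nm[idx[2]])
}

# Parabolic refinement of a matrix maximum along both axes.
.refine_eem_peak <- function(x, i, j) {
  ex <- x$excitation_nm[i]; em <- x$emission_nm[j]
  if (i > 1L && i < length(x$excitation_nm)) {
    v <- .parabolic_vertex(x$excitation_nm[(i - 1):(i + 1)],
                           x$intensity[(i - 1):(i + 1), j])
    if (is.finite(v) && v >= x$excitation_nm[i - 1] && v <= x$excitation_nm[i + 1]) ex <- v
  }
  if (j > 1L && j < length(x$emission_nm)) {
    v <- .parabolic_vertex(x$emission_nm[(j - 1):(j + 1)],
                           x$intensity[i, (j - 1):(j + 1)])
    if (is.finite(v) && v >= x$emission_nm[j - 1] && v <= x$emission_nm[j + 1]) em <- v
  }
  c(ex = ex, em = em)
}

#' Locate fluorescence and Rayleigh peaks in an excitation-emission matrix
#'
#' Rayleigh scattering ridges are identified geometrically (first order
#' along `em = ex`, second order along `em = 2 ex`, within
#' `ridge_tol_nm`) and masked; fluorescence peaks are local maxima of the
#' remaining cells. Peak 1 (tryptophan/tyrosine fluorescence) is the
#' strongest maximum with excitation in `peak1_ex_window`; peak 2
#' (polypeptide backbone) the strongest in `peak2_ex_window`.
#'
#' @param x An [eem].
#' @param ridge_tol_nm Half-width of the Rayleigh ridge bands (default 5).
#' @param peak1_ex_window,peak2_ex_window Excitation windows for assigning
#'   peaks 1 and 2 (defaults 260-300 and 220-250 nm).
#' @param min_rel_intensity Local maxima below this fraction of the global
#'   off-ridge maximum are ignored (default 0.05).
#' @return An object of class `eem_peaks`: `rayleigh_1`, `rayleigh_2`
#'   (ridge summaries), `peak1`, `peak2` (each `NULL` or a list with
#'   `excitation_nm`, `emission_nm`, `intensity`), and `all_peaks` (data
#'   frame of every off-ridge local maximum found).
#' @export
find_eem_peaks <- function(x, ridge_tol_nm = 5,
                           peak1_ex_window = c(260, 300),
                           peak2_ex_window = c(220, 250),
                           min_rel_intensity = 0.05) {
  stopifnot(inherits(x, "eem"))
  masks <- .ridge_masks(x, ridge_tol_nm)
  off <- !(masks$r1 | masks$r2)
  ray1 <- .ridge_summary(x, masks$r1)
  ray2 <- .ridge_summary(x, masks$r2)
  nI <- length(x$excitation_nm); nJ <- length(x$emission_nm)
  floor_int <- if (any(off)) max(x$intensity[off]) * min_rel_intensity else Inf
  found <- list()
  if (any(off) && max(x$intensity[off]) > 0) {
    for (i in seq_len(nI)) {
      for (j in seq_len(nJ)) {
        if (!off[i, j]) next
        v <- x$intensity[i, j]
        if (v < floor_int || v <= 0) next
        ii <- max(1L, i - 1L):min(nI, i + 1L)
        jj <- max(1L, j - 1L):min(nJ, j + 1L)
        neigh <- x$intensity[ii, jj]
        # strict local maximum over the 8-neighbourhood (plateaus rejected)
        if (v < max(neigh) || sum(neigh == v) > 1L) next
        pos <- .refine_eem_peak(x, i, j)
        found[[length(found) + 1L]] <- data.frame(
          excitation_nm = unname(pos["ex"]), emission_nm = unname(pos["em"]),
          intensity = v)
      }
    }
  }
  all_peaks <- if (length(found)) do.call(rbind, found) else
    data.frame(excitation_nm = numeric(0), emission_nm = numeric(0),
               intensity = numeric(0))
  rownames(all_peaks) <- NULL
  pick <- function(window) {
    cand <- all_peaks[all_peaks$excitation_nm >= window[1] &
                      all_peaks$excitation_nm <= window[2], , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    best <- cand[which.max(cand$intensity), ]
    list(excitation_nm = best$excitation_nm, emission_nm = best$emission_nm,
         intensity = best$intensity)
  }
  structure(
    list(rayleigh_1 = ray1, rayleigh_2 = ray2,
         peak1 = pick(peak1_ex_window), peak2 = pick(peak2_ex_window),
         all_peaks = all_peaks, ridge_tol_nm = ridge_tol_nm),
    class = "eem_peaks"
  )
}

#' Compare peak intensities between two excitation-emission matrices
#'
#' Fractional intensity drop of the named peak from a free-protein EEM to a
#' complex EEM (e.g. 0.35 = 35% loss).
#'
#' @param free,complex [eem] objects.
#' @param peak `"peak1"` or `"peak2"`.
#' @param ... Passed to [find_eem_peaks()].
#' @return Fractional drop `1 - I_complex / I_free`.
#' @export
eem_peak_drop <- function(free, complex, peak = "peak1", ...) {
  pf <- find_eem_peaks(free, ...)[[peak]]
  pc <- find_eem_peaks(complex, ...)[[peak]]
  if (is.null(pf) || is.null(pc)) {
    stop("requested peak not found in both matrices", call. = FALSE)
  }
  1 - pc$intensity / pf$intensity
}

#' UV/Vis absorption titration analysis
#'
#' Tracks the two protein absorption bands across a titration: peak 1
#' (~207 nm, n->pi* transitions of the peptide backbone) and peak 2
#' (~280 nm, pi->pi* transitions of the aromatic residues); reports
#' per-concentration positions/intensities and the shift of each band from
#' the free protein to the highest ligand concentration.
#'
#' @param spectra List of [absorption_spectrum] objects ordered by
#'   concentration; the first is the free protein.
#' @param quencher_conc_M Matching concentrations (mol/L).
#' @param peak1_window,peak2_window Search windows, nm (defaults 200-230
#'   and 255-310).
#' @param threshold_nm Shift classification threshold (default 2).
#' @return An object of class `uvvis_result`: `table` (per-concentration
#'   peaks), `shift_peak1`, `shift_peak2` (`peak_shift` objects, `NULL`
#'   when only one spectrum is given).
#' @export
uvvis_analysis <- function(spectra, quencher_conc_M,
                           peak1_window = c(200, 230),
                           peak2_window = c(255, 310),
                           threshold_nm = 2) {
  if (length(spectra) != length(quencher_conc_M)) {
    stop("spectra and quencher_conc_M lengths differ", call. = FALSE)
  }
  tab <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    p1 <- peak_position(spectra[[i]], peak1_window)
    p2 <- peak_position(spectra[[i]], peak2_window)
    data.frame(quencher_conc_M = quencher_conc_M[i],
               peak1_nm = p1$peak_nm, peak1_abs = p1$peak_intensity,
               peak2_nm = p2$peak_nm, peak2_abs = p2$peak_intensity)
  }))
  s1 <- s2 <- NULL
  if (length(spectra) > 1L) {
    last <- spectra[[length(spectra)]]
    s1 <- measure_shift(spectra[[1]], last, threshold_nm, peak1_window)
    s2 <- measure_shift(spectra[[1]], last, threshold_nm, peak2_window)
  }
  structure(list(table = tab, shift_peak1 = s1, shift_peak2 = s2),
            class = "uvvis_result")
}
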