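# Site-marker competitive displacement. Ketoprofen (KPF) marks Sudlow
# site I (subdomain IIA), ibuprofen (IBF) Sudlow site II (subdomain IIIA).
# The probe-displacement ratio F2/F1 compares complex fluorescence with and
# without the probe: a falling ratio means the marker competes for the
# ligand's site.

#' Probe displacement ratio
#'
#' `ratio = F2 / F1`, where F2 and F1 are the fluorescence intensities of
#' the ligand/albumin complex in the presence and absence of the site
#' marker. Vectorised.
#'
#' @param F2 Intensity with probe (>= 0).
#' @param F1 Intensity without probe (> 0).
#' @return F2/F1.
#' @export
displacement_ratio <- function(F2, F1) {
  if (any(F1 <= 0)) stop("F1 must be positive", call. = FALSE)
  if (any(F2 < 0)) stop("F2 must be non-negative", call. = FALSE)
  F2 / F1
}

#' Default marker-to-site mapping
#'
#' @param probe_id `"KPF"` (ketoprofen, Sudlow site I) or `"IBF"`
#'   (ibuprofen, Sudlow site II).
#' @return `"SudlowI"` or `"SudlowII"`.
#' @export
marker_site <- function(probe_id) {
  switch(toupper(probe_id),
         KPF = "SudlowI", IBF = "SudlowII",
         stop("unknown site marker: ", probe_id, call. = FALSE))
}

#' Displacement curve for one site marker
#'
#' @param probe_id Marker label (e.g. `"KPF"`, `"IBF"`).
#' @param probe_conc_M Increasing probe concentrations, mol/L.
#' @param ratio Positive F2/F1 ratios, one per concentration.
#' @param site_marked `"SudlowI"` or `"SudlowII"`; defaults to
#'   [marker_site()] of `probe_id`.
#' @return An object of class `displacement_curve`.
#' @export
displacement_curve <- function(probe_id, probe_conc_M, ratio,
                               site_marked = marker_site(probe_id)) {
  probe_conc_M <- as.numeric(probe_conc_M)
  ratio <- as.numeric(ratio)
  if (length(probe_conc_M) != length(ratio)) {
    stop("probe_conc_M and ratio must have the same length", call. = FALSE)
  }
  if (length(probe_conc_M) > 1L && any(diff(probe_conc_M) < 0)) {
    stop("probe concentrations must be increasing", call. = FALSE)
  }
  if (any(ratio <= 0)) stop("ratios must be positive", call. = FALSE)
  site_marked <- match.arg(site_marked, c("SudlowI", "SudlowII"))
  structure(list(probe_id = as.character(probe_id)[1],
                 probe_conc_M = probe_conc_M, ratio = ratio,
                 site_marked = site_marked),
            class = "displacement_curve")
}

#' Infer the binding site from marker displacement curves
#'
#' A marker "displaces" the ligand when the ratio at its highest probe
#' concentration drops below `threshold`. Decision table: only the site-I
#' marker displaces -> `"SudlowI"`; only the site-II marker ->
#' `"SudlowII"`; both -> `"ambiguous"`; neither -> `"surface_or_other"`
#' (binding outside both classical pockets, e.g. on the protein surface).
#'
#' @param curves A [displacement_curve] or list of them (one per marker),
#'   each with >= 2 probe concentrations.
#' @param threshold Displacement threshold on the final ratio (default
#'   0.8).
#' @return An object of class `site_call` with fields `site`,
#'   `displaced_by` (probe ids) and `threshold_used`.
#' @export
infer_site <- function(curves, threshold = 0.8) {
  if (inherits(curves, "displacement_curve")) curves <- list(curves)
  if (length(curves) == 0L) stop("no displacement curves given", call. = FALSE)
  ok <- vapply(curves, function(cv) length(cv$ratio) >= 2L, logical(1))
  if (!all(ok)) {
    stop("each displacement curve needs >= 2 probe concentrations", call. = FALSE)
  }
  final_ratio <- vapply(curves, function(cv) cv$ratio[length(cv$ratio)], numeric(1))
  displaces <- final_ratio < threshold
  sites <- vapply(curves, `[[`, character(1), "site_marked")
  ids <- vapply(curves, `[[`, character(1), "probe_id")
  hit1 <- any(displaces & sites == "SudlowI")
  hit2 <- any(displaces & sites == "SudlowII")
  site <- if (hit1 && hit2) "ambiguous"
          else if (hit1) "SudlowI"
          else if (hit2) "SudlowII"
          else "surface_or_other"
  structure(
    list(site = site, displaced_by = ids[displaces],
         final_ratios = stats::setNames(final_ratio, ids),
         threshold_used = threshold),
    class = "site_call"
  )
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("<site_call> %s (displaced by: %s; threshold %.2f)\n", x$site,
              if (length(x$displaced_by)) paste(x$displaced_by, collapse = ", ") else "none",
              x$threshold_used))
  invisible(x)
}
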