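# Study orchestration: run every stage on a directory of spectral files,
# assemble one report (JSON canonical; the text table is derived from it).

#' Study configuration
#'
#' Paths to the spectral inputs of one ligand/protein study plus the
#' analysis knobs. Only the quenching titrations are mandatory; absent
#' optional inputs simply produce absent report sections.
#'
#' @param label Complex label, e.g. `"EPX/HSA"`.
#' @param titration_paths Character vector of per-temperature titration
#'   CSVs (mandatory; temperatures are read from file metadata and must be
#'   distinct).
#' @param displacement_paths Optional named character vector of
#'   displacement-curve CSVs.
#' @param synchronous_paths Optional character vector of synchronous-scan
#'   CSVs.
#' @param eem_paths Optional named character vector with elements `free`
#'   and/or `complex`.
#' @param uvvis_path Optional UV/Vis titration CSV.
#' @param cd_path Optional CD CSV.
#' @param tau0_s Fluorophore lifetime for K_q (default 1e-8 s).
#' @param shift_threshold_nm Peak-shift classification threshold (default
#'   2).
#' @param displacement_threshold Site-marker displacement threshold
#'   (default 0.8).
#' @param seed Seed echoed into the report (default 1).
#' @return An object of class `study_config`.
#' @export
study_config <- function(label, titration_paths,
                         displacement_paths = NULL,
                         synchronous_paths = NULL,
                         eem_paths = NULL,
                         uvvis_path = NULL,
                         cd_path = NULL,
                         tau0_s = 1e-8,
                         shift_threshold_nm = 2,
                         displacement_threshold = 0.8,
                         seed = 1L) {
  if (length(titration_paths) < 1L) {
    stop("at least one titration file is required", call. = FALSE)
  }
  all_paths <- c(titration_paths, displacement_paths, synchronous_paths,
                 eem_paths, uvvis_path, cd_path)
  missing <- all_paths[!file.exists(all_paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(label = label, titration_paths = titration_paths,
         displacement_paths = displacement_paths,
         synchronous_paths = synchronous_paths,
         eem_paths = eem_paths, uvvis_path = uvvis_path, cd_path = cd_path,
         tau0_s = tau0_s, shift_threshold_nm = shift_threshold_nm,
         displacement_threshold = displacement_threshold,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run a full binding study
#'
#' Executes the stages in dependency order: quenching ratios and
#' Stern-Volmer fits per temperature, mechanism classification, Hill
#' binding parameters per temperature, van't Hoff thermodynamics with
#' force classification; then, where inputs are present, site-marker
#' displacement inference and the structural analyses (synchronous, EEM,
#' UV/Vis, CD). Every default-filter action (excluded enhancement points,
#' clipped percentages) is collected into `warnings`.
#'
#' @param config A [study_config].
#' @return An object of class `study_report` (nested list; see
#'   [write_report()] for serialisation).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  warnings <- character(0)

  series_list <- lapply(config$titration_paths, read_titration)
  temps <- vapply(series_list, `[[`, numeric(1), "temperature_K")
  if (anyDuplicated(temps)) {
    dup <- temps[duplicated(temps)][1]
    files <- config$titration_paths[temps == dup]
    stop(sprintf("temperature %g K appears in more than one titration file: %s",
                 dup, paste(files, collapse = " and ")), call. = FALSE)
  }
  ord <- order(temps)
  series_list <- series_list[ord]
  temps <- temps[ord]

  sv_results <- list(); binding_results <- list()
  for (i in seq_along(series_list)) {
    ratios <- quench_ratios(series_list[[i]])
    sv <- stern_volmer_fit(ratios, tau0_s = config$tau0_s)
    if (length(sv$excluded)) {
      warnings <- c(warnings, sprintf(
        "T = %g K: %d enhancement point(s) (F0/F < 1) excluded from the Stern-Volmer fit",
        temps[i], length(sv$excluded)))
    }
    hb <- hill_fit(series_list[[i]])
    drop_enh <- hb$dropped[hb$dropped$reason != "zero concentration", , drop = FALSE]
    if (nrow(drop_enh)) {
      warnings <- c(warnings, sprintf(
        "T = %g K: %d point(s) with F >= F0 dropped from the double-log fit",
        temps[i], nrow(drop_enh)))
    }
    sv_results[[i]] <- sv
    binding_results[[i]] <- hb
  }
  names(sv_results) <- names(binding_results) <- as.character(temps)

  mechanism <- if (length(sv_results) >= 2L) classify_mechanism(sv_results) else NULL
  thermo <- if (length(binding_results) >= 2L) thermo_analysis(binding_results) else NULL

  site <- NULL
  if (!is.null(config$displacement_paths)) {
    curves <- lapply(config$displacement_paths, read_displacement)
    site <- infer_site(curves, threshold = config$displacement_threshold)
  }

  synchronous <- NULL
  if (!is.null(config$synchronous_paths)) {
    synchronous <- lapply(config$synchronous_paths, function(p) {
      synchronous_analysis(read_synchronous(p),
                           threshold_nm = config$shift_threshold_nm)
    })
  }

  eem_section <- NULL
  if (!is.null(config$eem_paths)) {
    mats <- lapply(config$eem_paths, read_eem)
    eem_section <- lapply(mats, find_eem_peaks)
    if (all(c("free", "complex") %in% names(mats))) {
      eem_section$peak1_drop <- tryCatch(
        eem_peak_drop(mats$free, mats$complex, "peak1"),
        error = function(e) NA_real_)
    }
  }

  uvvis <- NULL
  if (!is.null(config$uvvis_path)) {
    uv <- read_uvvis(config$uvvis_path)
    uvvis <- uvvis_analysis(uv$spectra, uv$quencher_conc_M,
                            threshold_nm = config$shift_threshold_nm)
  }

  cd_section <- NULL
  if (!is.null(config$cd_path)) {
    ss <- withCallingHandlers(
      secondary_structure(read_cd(config$cd_path)),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    cd_section <- ss
  }

  structure(
    list(schema_version = "1.0",
         label = config$label,
         config = list(tau0_s = config$tau0_s,
                       shift_threshold_nm = config$shift_threshold_nm,
                       displacement_threshold = config$displacement_threshold,
                       seed = config$seed),
         temperatures_K = temps,
         stern_volmer = sv_results,
         mechanism = mechanism,
         binding = binding_results,
         thermodynamics = thermo,
         site = site,
         synchronous = synchronous,
         eem = eem_section,
         uvvis = uvvis,
         cd = cd_section,
         warnings = warnings),
    class = "study_report"
  )
}

# Strip classes/attributes so jsonlite serialises plainly.
.plain <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .plain)
    attributes(x) <- list(names = names(x))
    x
  } else {
    unname(unclass(x))
  }
}

#' Write a study report to JSON
#'
#' JSON is the canonical report format; [render_binding_table()] derives
#' its text table from the same object.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ser <- report
  class(ser) <- NULL
  # data frames serialise as column objects for stable round-tripping
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", force = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Render the binding/thermodynamics summary table
#'
#' Text table with the conventional columns — complex, T (K), K_A (L/mol,
#' scientific notation), n, dG, dH, dS (2-decimal energies) — derived from
#' the report's binding and thermodynamics sections.
#'
#' @param report A `study_report` (or a list of them for a multi-complex
#'   table).
#' @return Character vector of table lines (also printed-friendly via
#'   `cat`).
#' @export
render_binding_table <- function(report) {
  reports <- if (inherits(report, "study_report")) list(report) else report
  header <- sprintf("%-10s %6s %12s %6s %10s %10s %12s",
                    "Complex", "T (K)", "K_A (L/mol)", "n",
                    "dG (kJ/mol)", "dH (kJ/mol)", "dS (J/mol K)")
  lines <- header
  for (rp in reports) {
    if (is.null(rp$thermodynamics)) next
    th <- rp$thermodynamics
    for (k in seq_along(rp$binding)) {
      b <- rp$binding[[k]]
      tK <- b$temperature_K
      lines <- c(lines, sprintf(
        "%-10s %6g %12s %6.2f %10.2f %10s %12s",
        if (k == 1L) rp$label else "", tK,
        format(b$K_A, digits = 3, scientific = TRUE), b$n,
        th$delta_G_by_T[as.character(tK)],
        if (k == 1L) sprintf("%.2f", th$delta_H) else "",
        if (k == 1L) sprintf("%.2f", th$delta_S) else ""))
    }
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %s: %d temperature(s)\n", x$label,
              length(x$temperatures_K)))
  if (!is.null(x$mechanism)) cat("  mechanism:", x$mechanism$mechanism, "\n")
  if (!is.null(x$thermodynamics)) {
    cat(sprintf("  dH = %.2f kJ/mol, dS = %.2f J/(mol K), force = %s\n",
                x$thermodynamics$delta_H, x$thermodynamics$delta_S,
                x$thermodynamics$force_class$label))
  }
  if (!is.null(x$site)) cat("  site:", x$site$site, "\n")
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  invisible(x)
}
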