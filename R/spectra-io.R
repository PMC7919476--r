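# Delimited-text readers/writers. Dialect: comma-separated, UTF-8, one
# header row; metadata (and generator ground truth, when present) carried
# as leading "#! key: value" comment lines so no expected value ever needs
# to be hard-coded elsewhere.

.fmt <- function(x) sprintf("%.17g", x)   # bit-identical double round trip

.write_meta <- function(meta) {
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) paste(.fmt(v), collapse = ",") else paste(v, collapse = ",")
    sprintf("#! %s: %s", k, v)
  }, character(1))
}

.read_meta <- function(lines) {
  ml <- grep("^#!", lines, value = TRUE)
  meta <- list()
  for (l in ml) {
    kv <- sub("^#!\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:\\s*", "", kv))
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    meta[[trimws(k)]] <- if (!anyNA(num)) num else trimws(parts)
  }
  meta
}

.read_csv_body <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!grepl("^#", lines)]
  con <- textConnection(body)
  on.exit(close(con))
  dat <- utils::read.csv(con, check.names = FALSE)
  list(meta = .read_meta(lines), data = dat)
}

#' Read a fluorescence titration series from CSV
#'
#' Expects a comma-separated file whose first column is the wavelength grid
#' and whose remaining columns are intensities ordered by quencher
#' concentration. Metadata (protein id/concentration, quencher
#' concentrations, temperature, excitation wavelength) is taken from
#' leading `#! key: value` lines and can be supplied or overridden through
#' `metadata`.
#'
#' @param path Path to the CSV file.
#' @param metadata Optional named list overriding/supplementing file
#'   metadata; recognised keys: `protein_id`, `protein_conc_M`,
#'   `quencher_conc_M`, `temperature_K`, `excitation_nm`.
#' @return A validated [titration_series]. Any `truth_*` metadata found in
#'   the file is attached as the `"truth"` attribute.
#' @export
read_titration <- function(path, metadata = list()) {
  parsed <- .read_csv_body(path)
  meta <- utils::modifyList(parsed$meta, metadata)
  dat <- parsed$data
  need <- c("protein_id", "protein_conc_M", "quencher_conc_M", "temperature_K")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("missing titration metadata: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  q <- as.numeric(meta$quencher_conc_M)
  if (ncol(dat) - 1L != length(q)) {
    stop(sprintf(
      "file has %d intensity columns but metadata lists %d quencher concentrations",
      ncol(dat) - 1L, length(q)), call. = FALSE)
  }
  ex <- if (!is.null(meta$excitation_nm)) meta$excitation_nm else NA_real_
  grid <- as.numeric(dat[[1]])
  spectra <- lapply(seq_along(q), function(i) {
    emission_spectrum(grid, as.numeric(dat[[i + 1L]]), ex)
  })
  out <- titration_series(meta$protein_id, meta$protein_conc_M, q, spectra,
                          meta$temperature_K)
  truth <- meta[grep("^truth_", names(meta))]
  if (length(truth)) attr(out, "truth") <- truth
  out
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration()]: numeric payload round-trips
#' bit-identically (17 significant digits).
#'
#' @param series A [titration_series].
#' @param path Output path.
#' @param extra_meta Optional named list of additional `#!` metadata lines
#'   (e.g. generator ground truth as `truth_*` keys).
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path, extra_meta = list()) {
  meta <- list(protein_id = series$protein_id,
               protein_conc_M = series$protein_conc_M,
               quencher_conc_M = series$quencher_conc_M,
               temperature_K = series$temperature_K)
  ex <- series$spectra[[1]]$excitation_nm
  if (is.finite(ex)) meta$excitation_nm <- ex
  meta <- c(meta, extra_meta)
  grid <- series$spectra[[1]]$wavelength_nm
  mat <- vapply(series$spectra, function(s) s$intensity, numeric(length(grid)))
  header <- paste(c("wavelength_nm",
                    sprintf("Q%02d", seq_along(series$quencher_conc_M))),
                  collapse = ",")
  rows <- apply(cbind(grid, mat), 1L, function(r) paste(.fmt(r), collapse = ","))
  writeLines(c(.write_meta(meta), header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a synchronous scan series
#'
#' Same dialect as [read_titration()] with one extra metadata key,
#' `delta_lambda_nm`; the first column is the scanned excitation
#' wavelength.
#'
#' @param path File path.
#' @param metadata Optional metadata overrides (see [read_titration()]).
#' @return A [synchronous_series].
#' @export
read_synchronous <- function(path, metadata = list()) {
  parsed <- .read_csv_body(path)
  meta <- utils::modifyList(parsed$meta, metadata)
  if (is.null(meta$delta_lambda_nm)) {
    stop("missing delta_lambda_nm metadata for synchronous scan", call. = FALSE)
  }
  series <- read_titration(path, metadata)
  synchronous_series(meta$delta_lambda_nm, series)
}

#' @rdname read_synchronous
#' @param sync A [synchronous_series] to write.
#' @param extra_meta Additional `#!` metadata.
#' @export
write_synchronous <- function(sync, path, extra_meta = list()) {
  write_titration(sync$series, path,
                  c(list(delta_lambda_nm = sync$delta_lambda_nm), extra_meta))
}

#' Read/write an excitation-emission matrix
#'
#' Matrix CSV: header row carries the excitation grid, first column the
#' emission grid, body the intensities (emission rows by excitation
#' columns on disk; stored internally as excitation x emission).
#'
#' @param path File path.
#' @return An [eem].
#' @export
read_eem <- function(path) {
  parsed <- .read_csv_body(path)
  dat <- parsed$data
  ex <- as.numeric(sub("^ex_", "", names(dat)[-1]))
  em <- as.numeric(dat[[1]])
  intensity <- t(as.matrix(dat[, -1, drop = FALSE]))
  dimnames(intensity) <- NULL
  eem(ex, em, intensity)
}

#' @rdname read_eem
#' @param x An [eem] to write.
#' @param extra_meta Additional `#!` metadata.
#' @export
write_eem <- function(x, path, extra_meta = list()) {
  header <- paste(c("emission_nm", sprintf("ex_%s", .fmt(x$excitation_nm))),
                  collapse = ",")
  body <- cbind(x$emission_nm, t(x$intensity))
  rows <- apply(body, 1L, function(r) paste(.fmt(r), collapse = ","))
  writeLines(c(.write_meta(extra_meta), header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a circular dichroism spectrum
#'
#' Two-column CSV (wavelength_nm, ellipticity_mdeg) with the MRE conversion
#' parameters (`protein_conc_M`, `n_residues`, `path_length_cm`) in `#!`
#' metadata lines or supplied via `metadata`.
#'
#' @param path File path.
#' @param metadata Optional metadata overrides.
#' @return A [cd_spectrum].
#' @export
read_cd <- function(path, metadata = list()) {
  parsed <- .read_csv_body(path)
  meta <- utils::modifyList(parsed$meta, metadata)
  need <- c("protein_conc_M", "n_residues", "path_length_cm")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("missing CD metadata: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- cd_spectrum(parsed$data[[1]], parsed$data[[2]], meta$protein_conc_M,
                     meta$n_residues, meta$path_length_cm)
  truth <- meta[grep("^truth_", names(meta))]
  if (length(truth)) attr(out, "truth") <- truth
  out
}

#' @rdname read_cd
#' @param cd A [cd_spectrum] to write.
#' @param extra_meta Additional `#!` metadata.
#' @export
write_cd <- function(cd, path, extra_meta = list()) {
  meta <- c(list(protein_conc_M = cd$protein_conc_M, n_residues = cd$n_residues,
                 path_length_cm = cd$path_length_cm), extra_meta)
  rows <- apply(cbind(cd$wavelength_nm, cd$ellipticity_mdeg), 1L,
                function(r) paste(.fmt(r), collapse = ","))
  writeLines(c(.write_meta(meta), "wavelength_nm,ellipticity_mdeg", rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a UV/Vis absorption titration
#'
#' Same layout as a titration file (wavelength first, one absorbance column
#' per quencher concentration).
#'
#' @param path File path.
#' @param metadata Optional metadata overrides (needs `quencher_conc_M`).
#' @return A list with `spectra` (list of [absorption_spectrum]) and
#'   `quencher_conc_M`.
#' @export
read_uvvis <- function(path, metadata = list()) {
  parsed <- .read_csv_body(path)
  meta <- utils::modifyList(parsed$meta, metadata)
  if (is.null(meta$quencher_conc_M)) {
    stop("missing quencher_conc_M metadata for UV/Vis titration", call. = FALSE)
  }
  q <- as.numeric(meta$quencher_conc_M)
  dat <- parsed$data
  if (ncol(dat) - 1L != length(q)) {
    stop("UV/Vis column count does not match quencher concentration count",
         call. = FALSE)
  }
  grid <- as.numeric(dat[[1]])
  spectra <- lapply(seq_along(q), function(i) {
    absorption_spectrum(grid, as.numeric(dat[[i + 1L]]))
  })
  list(spectra = spectra, quencher_conc_M = q)
}

#' @rdname read_uvvis
#' @param uv A list as returned by [read_uvvis()] or [simulate_uvvis()].
#' @param extra_meta Additional `#!` metadata.
#' @export
write_uvvis <- function(uv, path, extra_meta = list()) {
  meta <- c(list(quencher_conc_M = uv$quencher_conc_M), extra_meta)
  grid <- uv$spectra[[1]]$wavelength_nm
  mat <- vapply(uv$spectra, function(s) s$absorbance, numeric(length(grid)))
  header <- paste(c("wavelength_nm", sprintf("Q%02d", seq_along(uv$quencher_conc_M))),
                  collapse = ",")
  rows <- apply(cbind(grid, mat), 1L, function(r) paste(.fmt(r), collapse = ","))
  writeLines(c(.write_meta(meta), header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read/write a site-marker displacement curve
#'
#' Two-column CSV (probe_conc_M, ratio) with `probe_id` and `site_marked`
#' metadata.
#'
#' @param path File path.
#' @param metadata Optional metadata overrides.
#' @return A [displacement_curve].
#' @export
read_displacement <- function(path, metadata = list()) {
  parsed <- .read_csv_body(path)
  meta <- utils::modifyList(parsed$meta, metadata)
  if (is.null(meta$probe_id)) stop("missing probe_id metadata", call. = FALSE)
  site <- if (!is.null(meta$site_marked)) meta$site_marked else marker_site(meta$probe_id)
  displacement_curve(meta$probe_id, parsed$data[[1]], parsed$data[[2]], site)
}

#' @rdname read_displacement
#' @param curve A [displacement_curve] to write.
#' @param extra_meta Additional `#!` metadata.
#' @export
write_displacement <- function(curve, path, extra_meta = list()) {
  meta <- c(list(probe_id = curve$probe_id, site_marked = curve$site_marked),
            extra_meta)
  rows <- apply(cbind(curve$probe_conc_M, curve$ratio), 1L,
                function(r) paste(.fmt(r), collapse = ","))
  writeLines(c(.write_meta(meta), "probe_conc_M,ratio", rows), path,
             useBytes = TRUE)
  invisible(path)
}
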