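# Spectrum and table I/O: the JSON peak-list dialect (canonical fixture
# format, versioned and human-diffable), mzML read support via mzR, TSV
# abundance tables, and the YAML run manifest.

.peaklist_dialect_version <- 1L

#' Construct a spectrum peak list
#'
#' @param level `"MS1"` or `"MS2"`.
#' @param mz,intensity Numeric peak vectors (intensities must be >= 0).
#' @param charge Optional integer vector of per-peak charges (`NA` where
#'   unknown; MS1 peaks without charge are tolerated but cannot be matched).
#' @param precursor For MS2 (required): `list(mz =, charge =, window_da =)`.
#' @param scan_id Scan identifier.
#' @param family Family hint: `"H3"`, `"H4"` or `"unknown"`.
#' @return A `spectrum_peaklist`; peaks are stored sorted by m/z.
#' @export
spectrum_peaklist <- function(level = c("MS1", "MS2"), mz, intensity,
                              charge = NULL, precursor = NULL,
                              scan_id = "scan1", family = "unknown") {
  level <- match.arg(level)
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  if (is.null(charge)) charge <- rep(NA_integer_, length(mz))
  stopifnot(length(charge) == length(mz))
  if (level == "MS2") {
    if (is.null(precursor) || is.null(precursor$mz) || is.null(precursor$charge))
      stop("MS2 spectrum '", scan_id, "' lacks a precursor (mz, charge)")
    if (is.null(precursor$window_da)) precursor$window_da <- 3.4
  }
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]; charge <- charge[o]
    warning("peaks of scan '", scan_id, "' were unsorted; sorted by m/z")
  }
  structure(list(level = level,
                 peaks = tibble::tibble(mz = as.numeric(mz),
                                        intensity = as.numeric(intensity),
                                        charge = as.integer(charge)),
                 precursor = precursor, scan_id = as.character(scan_id),
                 family = family),
            class = "spectrum_peaklist")
}

#' @export
print.spectrum_peaklist <- function(x, ...) {
  cat(sprintf("<spectrum_peaklist> %s %s: %d peaks", x$level, x$scan_id,
              nrow(x$peaks)))
  if (!is.null(x$precursor))
    cat(sprintf(" (precursor %.4f m/z, z=%d)", x$precursor$mz, x$precursor$charge))
  cat("\n")
  invisible(x)
}

#' Read spectra from mzML or the JSON peak-list dialect
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"mzml"`. mzML reading
#'   requires the mzR package.
#' @return A list of [spectrum_peaklist()] objects (scan count preserved).
#' @export
read_spectra <- function(path, format = c("auto", "json", "mzml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, json = .read_spectra_json(path), mzml = .read_spectra_mzml(path))
}

.read_spectra_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$version)) stop("peak-list JSON lacks the mandatory 'version' field")
  lapply(doc$spectra, function(sp) {
    pk <- do.call(rbind, lapply(sp$peaks, function(p) {
      c(p[[1]], p[[2]], if (length(p) >= 3 && !is.null(p[[3]])) p[[3]] else NA)
    }))
    if (is.null(pk)) pk <- matrix(numeric(), ncol = 3)
    prec <- sp$precursor
    spectrum_peaklist(level = sp$level, mz = pk[, 1], intensity = pk[, 2],
                      charge = as.integer(pk[, 3]), precursor = prec,
                      scan_id = sp$scan_id,
                      family = if (is.null(sp$family)) "unknown" else sp$family)
  })
}

.read_spectra_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(f, i)
    lvl <- if (h$msLevel[i] >= 2) "MS2" else "MS1"
    prec <- NULL
    if (lvl == "MS2") {
      if (is.na(h$precursorMZ[i]) || h$precursorMZ[i] <= 0)
        stop("MS2 scan ", h$seqNum[i], " in ", basename(path),
             " lacks a precursor m/z")
      win <- 3.4
      if ("isolationWindowLowerOffset" %in% names(h) &&
          !is.na(h$isolationWindowLowerOffset[i]))
        win <- h$isolationWindowLowerOffset[i] + h$isolationWindowUpperOffset[i]
      prec <- list(mz = h$precursorMZ[i],
                   charge = if (is.na(h$precursorCharge[i])) NA_integer_
                            else as.integer(h$precursorCharge[i]),
                   window_da = win)
    }
    spectrum_peaklist(level = lvl, mz = pk[, 1], intensity = pk[, 2],
                      charge = NULL, precursor = prec,
                      scan_id = paste0("scan=", h$acquisitionNum[i]))
  })
}

#' Write spectra in the JSON peak-list dialect
#'
#' The dialect is versioned and lossless: `read_spectra()` round-trips the
#' structure field for field. Peaks are `[mz, intensity, charge-or-null]`
#' triples.
#'
#' @param spectra A list of [spectrum_peaklist()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_json <- function(spectra, path) {
  doc <- list(version = .peaklist_dialect_version,
              spectra = lapply(spectra, function(sp) {
                peaks <- lapply(seq_len(nrow(sp$peaks)), function(i) {
                  z <- sp$peaks$charge[i]
                  list(sp$peaks$mz[i], sp$peaks$intensity[i],
                       if (is.na(z)) NULL else z)
                })
                out <- list(level = sp$level, scan_id = sp$scan_id,
                            family = sp$family, peaks = peaks)
                if (!is.null(sp$precursor)) out$precursor <- sp$precursor
                out
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

.abundance_cols <- c("family", "notation", "sample", "condition", "tissue",
                     "abundance_percent")

#' Write a normalized proteoform abundance table as TSV
#'
#' Refuses unnormalized input: per (sample, family) abundances must sum to
#' 100 (+/- 1e-6). Columns: family, notation (parseable by
#' [parse_notation()]), sample, condition, tissue, abundance_percent.
#'
#' @param table Abundance tibble (see [normalize_abundance()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  names(table)[names(table) == "abundance"] <- "abundance_percent"
  stopifnot(all(.abundance_cols %in% names(table)))
  sums <- tapply(table$abundance_percent,
                 paste(table$sample, table$family), sum)
  off <- abs(sums - 100) > 1e-6
  if (any(off))
    stop("table is not normalized to 100 per (sample, family): ",
         paste(names(sums)[off], collapse = ", "))
  table <- table[order(table$family, table$sample, table$notation),
                 .abundance_cols]
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a proteoform abundance table written by [write_abundance_table()]
#' @param path TSV path.
#' @return A tibble with an `abundance` column (percent of family).
#' @export
read_abundance_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           family = "c", notation = "c", sample = "c",
                           condition = "c", tissue = "c",
                           abundance_percent = "d"))
  names(tbl)[names(tbl) == "abundance_percent"] <- "abundance"
  tbl
}

#' Run manifest: sample/condition/tissue/replicate bookkeeping
#'
#' @param samples Tibble with columns `sample`, `tissue` (`"BAT"`/`"liver"`),
#'   `condition` (`"TN"`/`"RT"`/`"SC"`), `replicate` (technical replicate
#'   index), and optionally `path`.
#' @return A validated `run_manifest` tibble.
#' @export
run_manifest <- function(samples) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample", "tissue", "condition", "replicate") %in% names(samples)))
  if (!all(samples$condition %in% c("TN", "RT", "SC")))
    stop("conditions are restricted to TN, RT, SC")
  if (!all(samples$tissue %in% c("BAT", "liver")))
    stop("tissues are restricted to BAT, liver")
  if (anyDuplicated(samples[, c("sample", "replicate")]))
    stop("(sample, replicate) pairs must be unique")
  class(samples) <- c("run_manifest", class(samples))
  samples
}

#' @rdname run_manifest
#' @param path YAML path.
#' @export
read_run_manifest <- function(path) {
  doc <- yaml::read_yaml(path)
  run_manifest(dplyr::bind_rows(lapply(doc$samples, tibble::as_tibble)))
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @export
write_run_manifest <- function(manifest, path) {
  doc <- list(version = 1L,
              samples = lapply(seq_len(nrow(manifest)), function(i)
                as.list(manifest[i, , drop = FALSE])))
  yaml::write_yaml(doc, path)
  invisible(path)
}
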