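# MS1 precursor assignment: convert charged MS1 peaks to neutral masses and
# accumulate intensity per isobaric proteoform class within the isolation
# window (full width; a precursor matches within +/- window/2 of the class
# mass).

#' Assign MS1 peaks to isobaric classes
#'
#' Each charged MS1 peak is converted to a neutral mass and matched to the
#' nearest class if within half the MS1 window (the window is interpreted as
#' the full isolation width). Intensities of peaks matching the same class
#' are summed over charge states and scans. Peaks without a charge, outside
#' the family scan range, or beyond the window stay unmatched; intensity is
#' conserved between the matched and unmatched pools. Equidistant ties break
#' deterministically toward the lower-mass class.
#'
#' @param spectra List of MS1 [spectrum_peaklist()] objects.
#' @param classes An [isobaric_classes()] object built on the configured
#'   mass scale.
#' @param config An [ms_config()].
#' @param family Family whose scan range applies (`NULL` to accept all m/z).
#' @return List with `$assignments` (per-peak tibble: scan_id, mz, charge,
#'   intensity, neutral, class_id, ppm, matched, in_range), `$observations`
#'   (per-class tibble: class_id, class_mass, intensity, n_peaks, mean_ppm)
#'   and `$n_ties`.
#' @export
assign_precursors <- function(spectra, classes, config = ms_config(),
                              family = NULL) {
  stopifnot(inherits(classes, "isobaric_classes"))
  cls <- classes$classes
  if (nrow(cls) == 0) stop("no isobaric classes supplied")
  rng <- if (is.null(family)) NULL else .scan_range(config, family)
  rows <- lapply(spectra, function(sp) {
    if (sp$level != "MS1") return(NULL)
    tibble::tibble(scan_id = sp$scan_id, mz = sp$peaks$mz,
                   charge = sp$peaks$charge, intensity = sp$peaks$intensity)
  })
  pk <- dplyr::bind_rows(rows)
  if (nrow(pk) == 0)
    return(list(assignments = tibble::tibble(), observations = tibble::tibble(),
                n_ties = 0L))
  pk$in_range <- if (is.null(rng)) TRUE else pk$mz >= rng[1] & pk$mz <= rng[2]
  pk$neutral <- ifelse(is.na(pk$charge), NA_real_,
                       (pk$mz - config$proton_da) * pk$charge)
  half <- config$ms1_window_da / 2
  n_ties <- 0L
  idx <- rep(NA_integer_, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (is.na(pk$neutral[i]) || !pk$in_range[i]) next
    d <- abs(cls$class_mass - pk$neutral[i])
    j <- which(d == min(d))
    if (length(j) > 1L) {        # tie: classes table is sorted by mass,
      n_ties <- n_ties + 1L      # so the first index is the lower-mass class
      j <- j[1L]
    }
    if (d[j] <= half) idx[i] <- j
  }
  pk$class_id <- cls$class_id[idx]
  pk$ppm <- ifelse(is.na(idx), NA_real_,
                   1e6 * (pk$neutral - cls$class_mass[idx]) / cls$class_mass[idx])
  pk$matched <- !is.na(pk$class_id)
  obs <- dplyr::summarise(
    dplyr::group_by(pk[pk$matched, , drop = FALSE], .data$class_id),
    intensity = sum(.data$intensity), n_peaks = dplyr::n(),
    mean_ppm = mean(.data$ppm), .groups = "drop")
  obs <- dplyr::left_join(obs, cls[, c("class_id", "class_mass")], by = "class_id")
  obs <- dplyr::arrange(obs[, c("class_id", "class_mass", "intensity",
                                "n_peaks", "mean_ppm")], .data$class_mass)
  list(assignments = pk, observations = obs, n_ties = n_ties)
}
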