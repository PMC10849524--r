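# Deterministic mass arithmetic for intact histones and their ETD fragments.
# All constants come from one embedded table (inst/extdata/mass_tables.json)
# so results are bit-stable across platforms.

# Residue monomer compositions (the 20 canonical amino acids).
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.mass_env <- new.env(parent = emptyenv())

.mass_tables <- function() {
  if (is.null(.mass_env$tables)) {
    path <- system.file("extdata", "mass_tables.json", package = "histoform")
    .mass_env$tables <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .mass_env$tables
}

.parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  toks <- regmatches(formula, m)[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  stats::setNames(n, el)
}

.formula_mass <- function(formula, scale) {
  el <- .mass_tables()$elements[[scale]]
  counts <- .parse_formula(formula)
  stopifnot(all(names(counts) %in% names(el)))
  sum(unlist(el[names(counts)]) * counts)
}

#' Proton mass used for m/z arithmetic
#' @return Mass of a proton in Da.
#' @export
proton_mass <- function() .mass_tables()$proton_da

#' Post-translational modification mass deltas
#'
#' Acetylation (`ac`) and mono/di/tri-methylation (`me1`, `me2`, `me3`) mass
#' additions on both mass scales. `me2` and `me3` are exact multiples of
#' `me1`; the unmodified state `un` has delta 0.
#'
#' @return A tibble with columns `ptm`, `mono_da`, `avg_da`.
#' @export
ptm_deltas <- function() {
  ac_m <- .formula_mass("C2H2O", "monoisotopic")
  ac_a <- .formula_mass("C2H2O", "average")
  me_m <- .formula_mass("CH2", "monoisotopic")
  me_a <- .formula_mass("CH2", "average")
  tibble::tibble(
    ptm = c("un", "ac", "me1", "me2", "me3"),
    mono_da = c(0, ac_m, me_m, 2 * me_m, 3 * me_m),
    avg_da = c(0, ac_a, me_a, 2 * me_a, 3 * me_a)
  )
}

.ptm_delta <- function(ptm, scale) {
  tab <- ptm_deltas()
  col <- if (scale == "monoisotopic") "mono_da" else "avg_da"
  i <- match(ptm, tab$ptm)
  if (anyNA(i)) stop("unknown PTM state(s): ", paste(ptm[is.na(i)], collapse = ", "))
  tab[[col]][i]
}

#' Construct a histone backbone sequence
#'
#' @param name Backbone name, e.g. `"H4"`.
#' @param residues One-letter amino-acid string (canonical alphabet only).
#' @param fixed_mods List of fixed modifications, each `list(position =, ptm =)`.
#'   Position 1 with `ptm = "ac"` encodes N-terminal acetylation.
#' @return A `backbone` object.
#' @export
backbone <- function(name, residues, fixed_mods = list()) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  aa <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(aa), names(.residue_formulas))
  if (length(bad) > 0)
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  for (fm in fixed_mods) {
    if (fm$position < 1 || fm$position > length(aa))
      stop("fixed-mod position out of range: ", fm$position)
  }
  structure(list(name = name, residues = aa, fixed_mods = fixed_mods),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat("<backbone>", x$name, sprintf("(%d aa", length(x$residues)),
      if (length(x$fixed_mods)) sprintf(", %d fixed mod(s))", length(x$fixed_mods)) else ")",
      "\n")
  invisible(x)
}

#' Embedded histone backbones
#'
#' Loads the shipped FASTA fixtures: mature murine H4 (102 aa, initiator Met
#' removed, fixed N-terminal acetylation) and the GluC-derived H3.2 tail
#' (residues 1-50, ending at the first Glu).
#'
#' @param name `"H4"` or `"H3.2_tail"`.
#' @return A [backbone()] object.
#' @export
histone_backbone <- function(name = c("H4", "H3.2_tail")) {
  name <- match.arg(name)
  path <- system.file("extdata", "backbones.fasta", package = "histoform")
  seqs <- .read_fasta(path)
  fixed <- if (name == "H4") list(list(position = 1L, ptm = "ac")) else list()
  backbone(name, seqs[[name]], fixed_mods = fixed)
}

.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(as.list(out))
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  grp <- cumsum(idx)[!idx]
  stats::setNames(lapply(split(lines[!idx], grp), paste, collapse = ""), id)
}

.validate_states <- function(bb, site_states) {
  if (length(site_states) == 0) return(invisible(NULL))
  sites <- names(site_states)
  if (is.null(sites) || any(!nzchar(sites)))
    stop("site states must be a named vector, names like 'K16'")
  pos <- as.integer(sub("^[A-Z]", "", sites))
  aa <- sub("[0-9]+$", "", sites)
  if (any(is.na(pos)) || any(pos < 1) || any(pos > length(bb$residues)))
    stop("modified site outside backbone: ", paste(sites[is.na(pos) | pos < 1 | pos > length(bb$residues)], collapse = ", "))
  actual <- bb$residues[pos]
  if (any(actual != aa) || any(aa != "K"))
    stop("PTMs are only supported on lysine side chains; offending site(s): ",
         paste(sites[actual != aa | aa != "K"], collapse = ", "))
  invisible(NULL)
}

#' Neutral mass of a proteoform
#'
#' Backbone mass (residues + water + fixed modifications) plus the sum of the
#' variable PTM deltas, on the requested mass scale.
#'
#' @param bb A [backbone()].
#' @param site_states Named character vector of variable PTM states, e.g.
#'   `c(K12 = "ac", K20 = "me2")`. Sites must be lysines of the backbone.
#' @param scale `"average"` (isotope-averaged, the default used for intact
#'   precursors) or `"monoisotopic"`.
#' @return Neutral mass in Da.
#' @export
proteoform_mass <- function(bb, site_states = character(), scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(inherits(bb, "backbone"))
  .validate_states(bb, site_states)
  site_states <- site_states[site_states != "un"]
  el <- .mass_tables()$elements[[scale]]
  res_mass <- vapply(.residue_formulas, .formula_mass, numeric(1), scale = scale)
  m <- sum(res_mass[bb$residues]) + 2 * el[["H"]] + el[["O"]]
  for (fm in bb$fixed_mods) m <- m + .ptm_delta(fm$ptm, scale)
  m + sum(.ptm_delta(unname(site_states), scale))
}

#' Convert m/z and charge to neutral mass (and back)
#'
#' Standard proton-adduct arithmetic: `neutral = (mz - proton) * z`.
#'
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral mass in Da.
#' @export
mz_to_neutral <- function(mz, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  if (any(mz <= proton_mass())) stop("m/z must exceed the proton mass")
  (mz - proton_mass()) * z
}

#' @rdname mz_to_neutral
#' @param mass Neutral mass in Da.
#' @export
neutral_to_mz <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  mass / z + proton_mass()
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be positive.
#' @return Signed ppm error `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' ETD c/z fragment ladders
#'
#' Neutral masses of the c (quasi-molecular, b + NH3) and z-dot (radical,
#' y - NH2) fragment series for a proteoform. A PTM at site i shifts c ions
#' with index >= i and z ions spanning the site; N-terminal fixed
#' acetylation shifts every c ion. `c[i] + z[L - i]` is constant
#' (= M + mass of H) for a fixed proteoform.
#'
#' @inheritParams proteoform_mass
#' @param scale Fragment mass scale; fragments are matched monoisotopically.
#' @return List with numeric vectors `c` and `z`, each of length `L - 1`
#'   (index i = number of residues in the fragment).
#' @export
etd_fragments <- function(bb, site_states = character(), scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  stopifnot(inherits(bb, "backbone"))
  L <- length(bb$residues)
  if (L < 2) stop("backbone must have at least 2 residues")
  .validate_states(bb, site_states)
  site_states <- site_states[site_states != "un"]
  el <- .mass_tables()$elements[[scale]]
  res_mass <- vapply(.residue_formulas, .formula_mass, numeric(1), scale = scale)
  per_res <- unname(res_mass[bb$residues])
  for (fm in bb$fixed_mods)
    per_res[fm$position] <- per_res[fm$position] + .ptm_delta(fm$ptm, scale)
  if (length(site_states) > 0) {
    pos <- as.integer(sub("^K", "", names(site_states)))
    per_res[pos] <- per_res[pos] + .ptm_delta(unname(site_states), scale)
  }
  csum <- cumsum(per_res)
  nh3 <- el[["N"]] + 3 * el[["H"]]
  nh2 <- el[["N"]] + 2 * el[["H"]]
  h2o <- 2 * el[["H"]] + el[["O"]]
  total <- csum[L]
  i <- seq_len(L - 1)
  list(
    c = csum[i] + nh3,                       # residues 1..i
    z = (total - csum[L - i]) + h2o - nh2    # residues L-i+1..L (z-dot)
  )
}

#' HPLC standard curves for histone quantitation
#'
#' Linear standard curves relating offline HPLC peak area to histone mass:
#' ug H3 = (area - 2.6558) / 14.221 and ug H4 = (area - 6.0114) / 31.215.
#'
#' @param family `"H3"` or `"H4"`.
#' @return A `standard_curve` object with `slope` and `intercept`.
#' @export
standard_curve <- function(family = c("H3", "H4")) {
  family <- match.arg(family)
  par <- switch(family,
    H3 = c(slope = 14.221, intercept = 2.6558),
    H4 = c(slope = 31.215, intercept = 6.0114)
  )
  structure(list(family = family, slope = unname(par["slope"]),
                 intercept = unname(par["intercept"])),
            class = "standard_curve")
}

#' Convert an HPLC peak area to micrograms of histone
#'
#' @param area Peak area (instrument units).
#' @param curve A [standard_curve()].
#' @return Micrograms of histone; may be negative for sub-intercept areas
#'   (the caller decides how to handle those).
#' @export
ug_from_peak_area <- function(area, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve slope must be nonzero")
  (area - curve$intercept) / curve$slope
}

#' Acquisition and search configuration
#'
#' @param ms1_window_da Full MS1 isolation width in Da (precursors match a
#'   class within +/- half this window).
#' @param frag_tol_ppm Fragment-ion match tolerance in ppm.
#' @param mass_scale Mass scale for intact-precursor matching.
#' @param scan_range_h3,scan_range_h4 Acquisition m/z ranges per family.
#' @return An `ms_config` object.
#' @export
ms_config <- function(ms1_window_da = 3.4, frag_tol_ppm = 10.0,
                      mass_scale = c("average", "monoisotopic"),
                      scan_range_h3 = c(585, 640), scan_range_h4 = c(700, 1400)) {
  mass_scale <- match.arg(mass_scale)
  stopifnot(ms1_window_da > 0, frag_tol_ppm > 0,
            scan_range_h3[1] < scan_range_h3[2],
            scan_range_h4[1] < scan_range_h4[2])
  structure(list(ms1_window_da = ms1_window_da, frag_tol_ppm = frag_tol_ppm,
                 proton_da = proton_mass(), mass_scale = mass_scale,
                 scan_range_h3 = scan_range_h3, scan_range_h4 = scan_range_h4),
            class = "ms_config")
}

.scan_range <- function(config, family) {
  switch(family,
         H3 = , H3.2 = , H3.2_tail = config$scan_range_h3,
         H4 = config$scan_range_h4,
         NULL)
}
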