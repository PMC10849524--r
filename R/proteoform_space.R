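# Combinatorial proteoform spaces, isobaric grouping, and the {} / <>
# notation used throughout reports: <> encloses the complete modification
# state of a molecule (a proteoform), {} a set of PTMs that must be present
# (a discrete-PTM, contains-style query).

.state_rank <- c(un = 0, ac = 1, me1 = 2, me2 = 3, me3 = 4)

#' PTM search-space schema for a histone family
#'
#' Schemas ship as editable YAML (`inst/extdata/ptm_schemas.yaml`). H4 allows
#' acetylation at K5/K8/K12/K16/K31 and K20 methylation (me1/2/3); the H3.2
#' tail allows K4/K36 methylation, K9/K27 acetylation or methylation, and
#' K14/K18/K23 acetylation.
#'
#' @param family `"H4"` or `"H3.2"`.
#' @return A `ptm_schema` object: `family`, `backbone`, and `sites`, a named
#'   list of allowed states per site (every site lists `"un"`), ordered by
#'   residue number.
#' @export
ptm_schema <- function(family = c("H4", "H3.2")) {
  family <- match.arg(family)
  path <- system.file("extdata", "ptm_schemas.yaml", package = "histoform")
  raw <- yaml::read_yaml(path)$schemas[[family]]
  sites <- raw$sites
  stopifnot(length(sites) > 0, !anyDuplicated(names(sites)),
            all(vapply(sites, function(s) "un" %in% s, logical(1))))
  pos <- as.integer(sub("^K", "", names(sites)))
  sites <- sites[order(pos)]
  structure(list(family = family, backbone = raw$backbone, sites = sites),
            class = "ptm_schema")
}

#' Enumerate every proteoform of a schema
#'
#' The cardinality is the product of per-site state counts (128 for H4,
#' 3200 for H3.2). Rows are in canonical order: lexicographic by site
#' (residue number) with state rank un < ac < me1 < me2 < me3, so outputs
#' are diff-stable.
#'
#' @param schema A [ptm_schema()].
#' @return A tibble with one character column per site plus `notation`.
#' @export
enumerate_proteoforms <- function(schema) {
  stopifnot(inherits(schema, "ptm_schema"))
  if (length(schema$sites) == 0) stop("empty schema")
  grid <- expand.grid(rev(schema$sites), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  tbl <- tibble::as_tibble(grid)
  tbl$notation <- apply(as.matrix(tbl), 1L, function(st) {
    .format_exact(schema$family, stats::setNames(st, names(schema$sites)))
  })
  attr(tbl, "family") <- schema$family
  tbl
}

.format_exact <- function(family, states) {
  mod <- states[states != "un"]
  paste0(family, "<", paste0(names(mod), unname(mod), collapse = ""), ">")
}

#' Compute proteoform masses for an enumeration
#'
#' @param proteoforms Output of [enumerate_proteoforms()].
#' @param schema The matching [ptm_schema()].
#' @param scale Mass scale (intact precursors default to isotope-averaged).
#' @return The input tibble with a `mass` column appended.
#' @export
proteoform_masses <- function(proteoforms, schema,
                              scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  bb <- histone_backbone(schema$backbone)
  base <- proteoform_mass(bb, character(), scale = scale)
  col <- if (scale == "monoisotopic") "mono_da" else "avg_da"
  delta <- stats::setNames(ptm_deltas()[[col]], ptm_deltas()$ptm)
  add <- rowSums(vapply(names(schema$sites),
                        function(s) unname(delta[proteoforms[[s]]]),
                        numeric(nrow(proteoforms))))
  proteoforms$mass <- base + add
  proteoforms
}

#' Group proteoforms into MS1-co-isolated isobaric classes
#'
#' Single-linkage clustering of intact masses at the MS1 isolation window:
#' proteoforms chain into one class while consecutive sorted masses are
#' within `ms1_window_da` of each other. Proteoforms in one class co-isolate
#' and co-fragment, so they must be disentangled at MS2.
#'
#' @param proteoforms Tibble with a `mass` column (see [proteoform_masses()]).
#' @param config An [ms_config()].
#' @return List of class `isobaric_classes`: `$members` (input tibble plus
#'   `class_id`) and `$classes` (tibble `class_id`, `class_mass` (mean),
#'   `width`, `n_members`), sorted by mass.
#' @export
isobaric_classes <- function(proteoforms, config = ms_config()) {
  if (nrow(proteoforms) == 0) {
    return(structure(list(members = proteoforms,
                          classes = tibble::tibble(class_id = integer(),
                                                   class_mass = numeric(),
                                                   width = numeric(),
                                                   n_members = integer())),
                     class = "isobaric_classes"))
  }
  stopifnot("mass" %in% names(proteoforms))
  o <- order(proteoforms$mass)
  m <- proteoforms$mass[o]
  new_class <- c(TRUE, diff(m) > config$ms1_window_da)
  id_sorted <- cumsum(new_class)
  class_id <- integer(nrow(proteoforms))
  class_id[o] <- id_sorted
  members <- proteoforms
  members$class_id <- class_id
  classes <- dplyr::summarise(dplyr::group_by(members, .data$class_id),
                              class_mass = mean(.data$mass),
                              width = max(.data$mass) - min(.data$mass),
                              n_members = dplyr::n(), .groups = "drop")
  classes <- dplyr::arrange(classes, .data$class_mass)
  structure(list(members = members, classes = classes),
            class = "isobaric_classes")
}

#' Parse the bracket notation for PTM queries
#'
#' `"H3.2<K9me2K27me1>"` is an exact query (angle brackets: the enclosed
#' PTMs are the only modifications; all other sites are unmodified).
#' `"{K9me2/3}"` is a contains query (curly brackets: the enclosed PTMs are
#' present; other sites are unconstrained). Combined states such as
#' `me2/3` (me2 OR me3) are allowed inside `{}` only. `{K9un}` queries the
#' unmodified state of a site.
#'
#' @param text A notation string, optionally prefixed by the family.
#' @return A `ptm_query`: list with `family` (or `NA`), `mode`
#'   (`"exact"`/`"contains"`), and `sites`, a named list of allowed states.
#' @export
parse_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^([A-Za-z0-9.]*)([{<])(.*)([}>])$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) == 0 ||
      !identical(unname(c("{" = "}", "<" = ">")[parts[3]]), parts[5]))
    stop("malformed notation: ", text)
  family <- if (nzchar(parts[2])) parts[2] else NA_character_
  mode <- if (parts[3] == "{") "contains" else "exact"
  body <- parts[4]
  sites <- list()
  while (nzchar(body)) {
    tok <- regexec("^(K[0-9]+)(un|ac|me[1-3](?:/[1-3])*)", body)
    tp <- regmatches(body, tok)[[1]]
    if (length(tp) == 0)
      stop("malformed token at '", body, "' in notation: ", text)
    site <- tp[2]
    state <- tp[3]
    if (site %in% names(sites)) stop("duplicate site ", site, " in: ", text)
    states <- if (grepl("/", state)) {
      if (mode == "exact")
        stop("combined state '", state, "' is only allowed inside {}: ", text)
      lv <- strsplit(state, "/")[[1]]
      paste0("me", c(sub("^me", "", lv[1]), lv[-1]))
    } else state
    bad <- setdiff(states, names(.state_rank))
    if (length(bad)) stop("unknown state token '", state, "' in: ", text)
    sites[[site]] <- states
    body <- substr(body, nchar(tp[1]) + 1L, nchar(body))
  }
  pos <- as.integer(sub("^K", "", names(sites)))
  sites <- sites[order(pos)]
  structure(list(family = family, mode = mode, sites = sites),
            class = "ptm_query")
}

#' Format a PTM query back to bracket notation
#'
#' Round-trip stable with [parse_notation()]: sites are emitted in residue
#' order, combined methyl states collapse to the `meX/Y` form.
#'
#' @param query A `ptm_query`.
#' @return A notation string.
#' @export
format_notation <- function(query) {
  stopifnot(inherits(query, "ptm_query"))
  br <- if (query$mode == "contains") c("{", "}") else c("<", ">")
  toks <- vapply(names(query$sites), function(site) {
    st <- query$sites[[site]]
    if (length(st) == 1L) return(paste0(site, st))
    if (!all(grepl("^me[1-3]$", st)))
      stop("only methyl states can be combined: ", paste(st, collapse = "/"))
    lv <- sort(as.integer(sub("^me", "", st)))
    paste0(site, "me", paste(lv, collapse = "/"))
  }, character(1))
  fam <- if (is.na(query$family)) "" else query$family
  paste0(fam, br[1], paste(toks, collapse = ""), br[2])
}

#' Match a query against enumerated proteoforms
#'
#' An exact query matches the single proteoform whose complete state it
#' spells out (unlisted sites unmodified); a contains query matches every
#' proteoform whose state at each queried site is among the allowed states.
#'
#' @param query A `ptm_query` or notation string.
#' @param proteoforms Tibble from [enumerate_proteoforms()] (site columns).
#' @param schema The matching [ptm_schema()] (used to validate query sites).
#' @return Logical vector over rows of `proteoforms`.
#' @export
query_matches <- function(query, proteoforms, schema) {
  if (is.character(query)) query <- parse_notation(query)
  stopifnot(inherits(query, "ptm_query"), inherits(schema, "ptm_schema"))
  if (!is.na(query$family) && query$family != schema$family)
    stop("query family ", query$family, " does not match schema family ",
         schema$family)
  bad <- setdiff(names(query$sites), names(schema$sites))
  if (length(bad))
    stop("site(s) not in ", schema$family, " schema: ", paste(bad, collapse = ", "))
  keep <- rep(TRUE, nrow(proteoforms))
  if (query$mode == "exact") {
    for (site in names(schema$sites)) {
      want <- if (site %in% names(query$sites)) query$sites[[site]] else "un"
      if (length(want) != 1L) stop("exact query cannot carry combined states")
      keep <- keep & proteoforms[[site]] == want
    }
  } else {
    for (site in names(query$sites))
      keep <- keep & proteoforms[[site]] %in% query$sites[[site]]
  }
  keep
}

# Named state vector (non-un only) for row i of an enumeration tibble.
.row_states <- function(proteoforms, schema, i) {
  st <- vapply(names(schema$sites), function(s) proteoforms[[s]][i], character(1))
  st[st != "un"]
}

# Per-proteoform side-chain acetyl and methyl counts from site columns.
.ptm_counts <- function(proteoforms, sites) {
  mat <- as.matrix(proteoforms[, sites, drop = FALSE])
  n_ac <- rowSums(mat == "ac")
  n_me <- rowSums((mat == "me1") + 2 * (mat == "me2") + 3 * (mat == "me3"))
  tibble::tibble(n_ac = n_ac, n_me = n_me)
}
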