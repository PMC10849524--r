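# The quantitation core: ETD c/z fragment matching at ppm tolerance over the
# co-isolated candidates of an isobaric class, construction of the binary
# fragment-evidence matrix, and non-negative least-squares apportionment of
# precursor intensity among positional isomers.

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b|| subject to x >= 0.
#'
#' @param A Numeric matrix (rows = observations, columns = unknowns).
#' @param b Numeric right-hand side.
#' @param tol Dual-feasibility tolerance (relative to the problem scale).
#' @return Numeric solution vector of length `ncol(A)`.
#' @export
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(A)) * max(abs(b), 1))
  x <- numeric(n)
  P <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  outer <- 0L
  while (any(!P) && max(w[!P]) > tol && outer < 30L * n) {
    outer <- outer + 1L
    free <- which(!P)
    P[free[which.max(w[free])]] <- TRUE
    repeat {
      s <- numeric(n)
      idx <- which(P)
      s[idx] <- qr.coef(qr(A[, idx, drop = FALSE]), b)
      s[idx][is.na(s[idx])] <- 0
      if (all(s[idx] > 0)) { x <- s; break }
      neg <- idx[s[idx] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- pmax(x + alpha * (s - x), 0)
      P[x <= 0 & P] <- FALSE
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

# Merge observed neutral masses within the fragment tolerance.
# Intensity-weighted mean mass per merged group; greedy left-to-right on the
# sorted masses, so ties resolve toward the lower mass.
.merge_observed <- function(mass, intensity, tol_ppm) {
  o <- order(mass)
  mass <- mass[o]; intensity <- intensity[o]
  gm <- numeric(0); gi <- numeric(0)
  for (k in seq_along(mass)) {
    n <- length(gm)
    if (n > 0 && abs(mass[k] - gm[n]) <= tol_ppm * 1e-6 * gm[n]) {
      wsum <- gi[n] + intensity[k]
      gm[n] <- if (wsum > 0) (gm[n] * gi[n] + mass[k] * intensity[k]) / wsum
               else (gm[n] + mass[k]) / 2
      gi[n] <- wsum
    } else {
      gm <- c(gm, mass[k]); gi <- c(gi, intensity[k])
    }
  }
  tibble::tibble(mass = gm, intensity = gi)
}

#' Match ETD fragments of co-isolated candidates to an MS2 spectrum
#'
#' Observed MS2 peaks are neutralized at their annotated charge (z = 1 when
#' uncharged), merged within the fragment tolerance, and matched against the
#' monoisotopic c/z ladders of every candidate proteoform of the precursor's
#' isobaric class. The result is the binary incidence matrix A (rows =
#' merged observed masses, columns = candidates; 1 iff the candidate has a
#' fragment within `frag_tol_ppm`) and the observed intensity vector b.
#' Peaks explained by no candidate are retained in the residual pool.
#'
#' @param ms2 An MS2 [spectrum_peaklist()].
#' @param candidates Tibble of candidate proteoforms (site columns +
#'   `notation`), normally the members of one isobaric class.
#' @param schema The matching [ptm_schema()].
#' @param config An [ms_config()].
#' @return A `fragment_evidence` object: `candidates`, `A`, `b`, `observed`
#'   (merged masses with `matched` flag), `residual` (unexplained pool).
#' @export
match_fragments <- function(ms2, candidates, schema, config = ms_config()) {
  stopifnot(inherits(ms2, "spectrum_peaklist"), ms2$level == "MS2")
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("candidate list must be non-empty")
  bb <- histone_backbone(schema$backbone)
  frag <- lapply(seq_len(nrow(candidates)), function(i) {
    st <- .row_states(candidates, schema, i)
    fl <- etd_fragments(bb, st, scale = "monoisotopic")
    sort(c(fl$c, fl$z))
  })
  z <- ifelse(is.na(ms2$peaks$charge), 1L, ms2$peaks$charge)
  neutral <- (ms2$peaks$mz - config$proton_da) * z
  obs <- .merge_observed(neutral, ms2$peaks$intensity, config$frag_tol_ppm)
  tol <- config$frag_tol_ppm * 1e-6
  A <- vapply(frag, function(f) {
    vapply(obs$mass, function(m) {
      i <- findInterval(m, f)
      lo <- max(1L, i); hi <- min(length(f), i + 1L)
      any(abs(m - f[lo:hi]) <= tol * f[lo:hi])
    }, logical(1))
  }, logical(nrow(obs)))
  A <- matrix(as.numeric(A), nrow = nrow(obs),
              dimnames = list(NULL, candidates$notation))
  matched <- rowSums(A) > 0
  structure(list(candidates = candidates, schema = schema,
                 A = A[matched, , drop = FALSE],
                 b = obs$intensity[matched],
                 observed = tibble::tibble(obs, matched = matched),
                 residual = obs[!matched, , drop = FALSE],
                 config = config, fragments = frag),
            class = "fragment_evidence")
}

#' Apportion precursor intensity among co-isolated proteoforms
#'
#' Solves min ||A x - b|| with x >= 0 over the fragment-evidence matrix and
#' normalizes x to fractions. Candidates with identical evidence columns are
#' indistinguishable: their pooled fraction is split uniformly and the
#' ambiguity flag is set. An all-zero (or empty) b yields a uniform split
#' with the ambiguity flag set. Apportionment is invariant to rescaling b.
#'
#' @param evidence A `fragment_evidence` from [match_fragments()].
#' @return List with `fractions` (named, sums to 1), `residual_norm`
#'   (relative, `||Ax - b|| / ||b||`), `ambiguous` flag, and
#'   `n_discriminating` (rows that differ between some pair of candidates).
#' @export
apportion <- function(evidence) {
  stopifnot(inherits(evidence, "fragment_evidence"))
  A <- evidence$A
  b <- evidence$b
  ncand <- ncol(A)
  notation <- colnames(A)
  if (length(b) == 0 || sum(b) == 0) {
    return(list(fractions = stats::setNames(rep(1 / ncand, ncand), notation),
                residual_norm = NA_real_, ambiguous = TRUE,
                n_discriminating = 0L))
  }
  key <- apply(A, 2L, paste, collapse = "")
  groups <- split(seq_len(ncand), key)
  Ag <- vapply(groups, function(idx) A[, idx[1]], numeric(nrow(A)))
  Ag <- matrix(Ag, nrow = nrow(A))
  xg <- nnls_solve(Ag, b)
  x <- numeric(ncand)
  for (g in seq_along(groups)) x[groups[[g]]] <- xg[g] / length(groups[[g]])
  ambiguous <- any(vapply(seq_along(groups), function(g)
    length(groups[[g]]) > 1L && xg[g] > 0, logical(1)))
  if (sum(x) == 0) {
    frac <- rep(1 / ncand, ncand)
    ambiguous <- TRUE
  } else frac <- x / sum(x)
  n_disc <- sum(apply(A, 1L, function(r) any(r != r[1])))
  list(fractions = stats::setNames(frac, notation),
       residual_norm = sqrt(sum((Ag %*% xg - b)^2)) / sqrt(sum(b^2)),
       ambiguous = ambiguous, n_discriminating = as.integer(n_disc))
}

#' Site-level localization status for a candidate proteoform
#'
#' A site is "unambiguous" when the observed matched fragments pin its state
#' down within the isobaric class: every alternative candidate that assigns
#' a different state to the site fails to explain at least one matched
#' fragment mass. With no matched fragments all sites are ambiguous.
#'
#' @param evidence A `fragment_evidence`.
#' @param candidate Notation string of a candidate in the evidence.
#' @return Tibble with `site`, `state`, `status` (`"unambiguous"` /
#'   `"ambiguous"`).
#' @export
localize <- function(evidence, candidate) {
  stopifnot(inherits(evidence, "fragment_evidence"))
  cand_idx <- match(candidate, colnames(evidence$A))
  if (is.na(cand_idx)) stop("candidate not in evidence: ", candidate)
  schema <- evidence$schema
  cands <- evidence$candidates
  sites <- names(schema$sites)
  states <- vapply(sites, function(s) cands[[s]][cand_idx], character(1))
  rows <- which(evidence$A[, cand_idx] == 1)
  status <- vapply(sites, function(s) {
    if (length(rows) == 0) return("ambiguous")
    alts <- which(cands[[s]] != states[[s]])
    if (length(alts) == 0) return("unambiguous")
    # an alternative "explains the same matched set" if it matches every
    # fragment mass the candidate matched
    explains_all <- vapply(alts, function(a)
      all(evidence$A[rows, a] == 1), logical(1))
    if (any(explains_all)) "ambiguous" else "unambiguous"
  }, character(1))
  tibble::tibble(site = sites, state = unname(states), status = unname(status))
}
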