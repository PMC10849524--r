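# From per-class apportioned fractions to normalized abundance tables,
# aggregate metrics ({} sums, bulk acetylation/methylation, acetyls and
# methyls per molecule), percentage-point + fold comparisons, and the
# multiple-testing procedures (Welch t, ANOVA + Tukey, Benjamini-Hochberg,
# and the Benjamini-Krieger-Yekutieli two-stage step-up).

#' Normalize per-class quantitation to a proteoform abundance table
#'
#' Proteoform abundance = MS1 class intensity x within-class apportioned
#' fraction, rescaled per (sample, technical replicate, family) to sum to
#' 100 percent of the family. Technical replicates are averaged after
#' normalization; samples with zero total intensity are dropped with a
#' warning.
#'
#' @param quant Tibble with columns `family`, `notation`, `sample`,
#'   `condition`, `tissue`, `replicate`, `class_intensity`, `fraction`.
#' @return Abundance tibble: `family`, `notation`, `sample`, `condition`,
#'   `tissue`, `abundance` (percent of family, replicate-averaged).
#' @export
normalize_abundance <- function(quant) {
  need <- c("family", "notation", "sample", "condition", "tissue",
            "replicate", "class_intensity", "fraction")
  stopifnot(all(need %in% names(quant)))
  quant$raw <- quant$class_intensity * quant$fraction
  totals <- dplyr::summarise(
    dplyr::group_by(quant, .data$family, .data$sample, .data$replicate),
    total = sum(.data$raw), .groups = "drop")
  dead <- totals$total <= 0
  if (any(dead)) {
    warning(sum(dead), " sample replicate(s) with zero total intensity dropped")
    totals <- totals[!dead, , drop = FALSE]
  }
  quant <- dplyr::inner_join(quant, totals,
                             by = c("family", "sample", "replicate"))
  quant$percent <- 100 * quant$raw / quant$total
  per_rep <- dplyr::summarise(
    dplyr::group_by(quant, .data$family, .data$notation, .data$sample,
                    .data$condition, .data$tissue, .data$replicate),
    percent = sum(.data$percent), .groups = "drop")
  # average technical replicates; a proteoform absent from one replicate
  # counts as 0 there, so divide by the replicate count of the sample
  nrep <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$family, .data$sample),
    n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$family, .data$notation, .data$sample,
                    .data$condition, .data$tissue),
    total_percent = sum(.data$percent), .groups = "drop")
  out <- dplyr::inner_join(out, nrep, by = c("family", "sample"))
  out$abundance <- out$total_percent / out$n_rep
  dplyr::arrange(out[, c("family", "notation", "sample", "condition",
                         "tissue", "abundance")],
                 .data$family, .data$sample, .data$notation)
}

# Per-row PTM state columns reconstructed from the notation strings.
.table_states <- function(table, schema) {
  notes <- unique(table$notation)
  qs <- lapply(notes, parse_notation)
  mat <- matrix("un", nrow = length(notes), ncol = length(schema$sites),
                dimnames = list(notes, names(schema$sites)))
  for (i in seq_along(qs)) {
    q <- qs[[i]]
    if (q$mode != "exact")
      stop("abundance tables must carry exact <> notation: ", notes[i])
    bad <- setdiff(names(q$sites), names(schema$sites))
    if (length(bad))
      stop("notation ", notes[i], " has site(s) outside the ",
           schema$family, " schema: ", paste(bad, collapse = ", "))
    for (s in names(q$sites)) mat[i, s] <- q$sites[[s]]
  }
  mat
}

#' Discrete-PTM abundance: sum of proteoforms matching a contains query
#'
#' Implements the `{}` semantics: the abundance of all proteoforms that
#' contain the queried modifications is summed, per sample.
#'
#' @param table Abundance tibble (see [normalize_abundance()]).
#' @param query Notation string (usually `{...}`) or `ptm_query`.
#' @param schema The family's [ptm_schema()]; defaults to the schema of the
#'   table's (single) family.
#' @return Tibble `sample`, `condition`, `tissue`, `value` (percent).
#' @export
discrete_ptm <- function(table, query, schema = NULL) {
  if (is.character(query)) query <- parse_notation(query)
  if (is.null(schema)) schema <- ptm_schema(unique(table$family))
  if (!is.na(query$family) && query$family != schema$family)
    stop("query family ", query$family, " does not match table family ",
         schema$family)
  states <- .table_states(table, schema)
  keep_note <- rep(TRUE, nrow(states))
  for (s in names(query$sites)) {
    bad <- setdiff(query$sites[[s]], schema$sites[[s]])
    if (!s %in% colnames(states) || length(bad))
      stop("query site/state not in ", schema$family, " schema: ", s)
    if (query$mode == "exact")
      keep_note <- keep_note & states[, s] %in% query$sites[[s]]
    else
      keep_note <- keep_note & states[, s] %in% query$sites[[s]]
  }
  if (query$mode == "exact") {
    for (s in setdiff(colnames(states), names(query$sites)))
      keep_note <- keep_note & states[, s] == "un"
  }
  table$keep <- keep_note[match(table$notation, rownames(states))]
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$sample, .data$condition, .data$tissue),
    value = sum(.data$abundance[.data$keep]), .groups = "drop")
  out
}

#' Bulk acetylation/methylation metrics per sample
#'
#' `percent_acetylated`: summed abundance of proteoforms with at least one
#' side-chain acetylation (H4's fixed N-terminal acetylation never counts).
#' `percent_methylated`: at least one methylated lysine.
#' `acetyls_per_molecule` / `methyls_per_molecule`: abundance-weighted mean
#' number of acetyl / methyl groups (me2 counts 2 methyls, me3 counts 3).
#'
#' @inheritParams discrete_ptm
#' @return Tibble with one row per sample and the four metrics.
#' @export
bulk_metrics <- function(table, schema = NULL) {
  if (is.null(schema)) schema <- ptm_schema(unique(table$family))
  states <- .table_states(table, schema)
  counts <- .ptm_counts(tibble::as_tibble(as.data.frame(states)),
                        colnames(states))
  i <- match(table$notation, rownames(states))
  table$n_ac <- counts$n_ac[i]
  table$n_me <- counts$n_me[i]
  dplyr::summarise(
    dplyr::group_by(table, .data$sample, .data$condition, .data$tissue),
    percent_acetylated = sum(.data$abundance[.data$n_ac >= 1]),
    percent_methylated = sum(.data$abundance[.data$n_me >= 1]),
    acetyls_per_molecule = sum(.data$abundance * .data$n_ac) / 100,
    methyls_per_molecule = sum(.data$abundance * .data$n_me) / 100,
    .groups = "drop")
}

#' Significance thresholds for comparisons
#' @param alpha Significance level (default 0.05).
#' @param fold_cutoff Fold-change cutoff (default 1.5; applied as >= cutoff
#'   or <= 1/cutoff).
#' @return A `stat_thresholds` list.
#' @export
stat_thresholds <- function(alpha = 0.05, fold_cutoff = 1.5) {
  stopifnot(alpha > 0, alpha < 1, fold_cutoff > 1)
  structure(list(alpha = alpha, fold_cutoff = fold_cutoff),
            class = "stat_thresholds")
}

#' Compare a metric between groups (pp + fold, Welch t or ANOVA + Tukey)
#'
#' Percentage-point change (`mean_a - mean_b`, the fraction of the genome
#' affected) and fold change (`mean_a / mean_b`, computed on group means)
#' are reported as independent metrics. Two groups get Welch's two-tailed
#' t-test; three or more get one-way ANOVA with Tukey HSD adjusted p per
#' pair. Volcano-style significance requires BOTH p < alpha and fold-change
#' beyond the cutoff; `pp_change` is never gated. Groups with fewer than
#' two observations yield descriptives only (p = NA).
#'
#' @param data Tibble with columns `value` and `group`.
#' @param metric Label carried into the output.
#' @param thresholds A [stat_thresholds()].
#' @return Tibble with one row per group pair: means, `pp_change`,
#'   `fold_change`, `p` (Welch or Tukey-adjusted), `anova_p` (3+ groups),
#'   `significant`.
#' @export
compare_groups <- function(data, metric = "metric",
                           thresholds = stat_thresholds()) {
  stopifnot(all(c("value", "group") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (length(groups) < 2) stop("need at least two groups")
  vals <- split(data$value, as.character(data$group))[groups]
  anova_p <- NA_real_
  tukey <- NULL
  if (length(groups) >= 3 && all(lengths(vals) >= 2)) {
    fit <- stats::aov(value ~ group, data = transform(data, group = factor(group)))
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tukey <- stats::TukeyHSD(fit)$group
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    ma <- mean(a); mb <- mean(b)
    p <- NA_real_
    if (length(groups) == 2) {
      if (length(a) >= 2 && length(b) >= 2) {
        p <- tryCatch(stats::t.test(a, b)$p.value,
                      error = function(e) if (isTRUE(all.equal(ma, mb))) 1 else NA_real_)
      }
    } else if (!is.null(tukey)) {
      key <- paste(pr[1], pr[2], sep = "-")
      alt <- paste(pr[2], pr[1], sep = "-")
      p <- if (key %in% rownames(tukey)) tukey[key, "p adj"]
           else if (alt %in% rownames(tukey)) tukey[alt, "p adj"]
           else NA_real_
    }
    fold <- ma / mb
    tibble::tibble(metric = metric, group_a = pr[1], group_b = pr[2],
                   n_a = length(a), n_b = length(b),
                   mean_a = ma, mean_b = mb,
                   pp_change = ma - mb, fold_change = fold,
                   p = p, anova_p = anova_p,
                   significant = !is.na(p) & p < thresholds$alpha &
                     (fold >= thresholds$fold_cutoff |
                        fold <= 1 / thresholds$fold_cutoff))
  })
  dplyr::bind_rows(rows)
}

#' Compare a PTM metric of an abundance table between conditions or tissues
#'
#' Computes per-sample values of `query` via [discrete_ptm()] (both `{}` and
#' `<>` queries) and runs [compare_groups()] over the chosen grouping.
#'
#' @inheritParams discrete_ptm
#' @param by Grouping column: `"condition"` or `"tissue"`.
#' @param thresholds A [stat_thresholds()].
#' @return See [compare_groups()].
#' @export
compare_metric <- function(table, query, by = c("condition", "tissue"),
                           schema = NULL, thresholds = stat_thresholds()) {
  by <- match.arg(by)
  vals <- discrete_ptm(table, query, schema)
  label <- if (is.character(query)) query else format_notation(query)
  data <- tibble::tibble(value = vals$value, group = vals[[by]])
  compare_groups(data, metric = label, thresholds = thresholds)
}

#' Benjamini-Hochberg adjusted p-values (linear step-up)
#'
#' Classic step-up adjustment: `q_(i) = min_{j >= i} (m/j) p_(j)`, capped
#' at 1.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted q-values in the original order; `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  .check_p(p)
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

.check_p <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  invisible(NULL)
}

.bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= alpha * seq_len(m) / m)
  r <- if (length(k)) max(k) else 0L
  rej <- logical(m)
  if (r > 0) rej[o[seq_len(r)]] <- TRUE
  rej
}

#' Two-stage linear step-up FDR (Benjamini, Krieger & Yekutieli)
#'
#' Stage one runs the linear step-up at alpha' = alpha / (1 + alpha) and
#' estimates the number of true nulls as m0 = m - r1; stage two reruns the
#' step-up at alpha' * m / m0. Discovery flags are monotone in the sorted
#' p-values.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param alpha Target FDR level.
#' @return List with `reject` (logical flags), `q` (adjusted values:
#'   BH-adjusted p scaled by `m0/m * (1 + alpha)`, capped at 1), `m0`, and
#'   `n_discoveries`.
#' @export
fdr_two_stage <- function(p, alpha = 0.05) {
  .check_p(p)
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  stage1 <- .bh_reject(p, alpha1)
  r1 <- sum(stage1)
  if (r1 == 0L || r1 == m) {
    reject <- stage1
    m0 <- m
    q <- pmin(1, bh_adjust(p) * (1 + alpha))
  } else {
    m0 <- m - r1
    reject <- .bh_reject(p, alpha1 * m / m0)
    q <- pmin(1, bh_adjust(p) * (m0 / m) * (1 + alpha))
  }
  list(reject = reject, q = q, m0 = as.integer(m0),
       n_discoveries = as.integer(sum(reject)))
}

#' Log2 fold-change cutoff implied by a percent fold-change threshold
#'
#' A 20 percent expression change corresponds to |log2 FC| >= |log2 1.2|
#' = 0.263 (3 dp).
#'
#' @param percent Percent change defining the cutoff (default 20).
#' @param digits Rounding applied to the reported cutoff (default 3, the
#'   precision at which the threshold is conventionally stated).
#' @return The absolute log2 fold-change cutoff.
#' @export
deg_log2fc_cutoff <- function(percent = 20, digits = 3) {
  round(abs(log2(1 + percent / 100)), digits)
}
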