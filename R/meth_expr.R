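# Differential-methylation and differential-expression filtering and the
# inverse promoter-methylation / expression integration (hypo-up,
# hyper-down classification).

#' Thresholds for methylation-expression integration
#'
#' Defaults follow the conventional filters: absolute percent-methylation
#' difference strictly greater than 5 points at q < 0.05 for differential
#' methylation; adjusted p < 0.05 with |log2 FC| >= 0.263 (a 20 percent
#' fold-change cutoff, boundary inclusive) for differential expression.
#' The asymmetric boundary conventions (> 5 exclusive, >= 0.263 inclusive)
#' mirror the inequality forms in which these filters are conventionally
#' stated.
#'
#' @param meth_diff_min Minimum absolute methylation difference
#'   (percentage points, exclusive).
#' @param q_max Methylation q-value cutoff (exclusive).
#' @param padj_max Expression adjusted-p cutoff (exclusive).
#' @param log2fc_min Minimum absolute log2 fold change (inclusive).
#' @return An `integration_thresholds` list.
#' @export
integration_thresholds <- function(meth_diff_min = 5, q_max = 0.05,
                                   padj_max = 0.05, log2fc_min = 0.263) {
  stopifnot(meth_diff_min > 0, q_max > 0, padj_max > 0, log2fc_min > 0)
  structure(list(meth_diff_min = meth_diff_min, q_max = q_max,
                 padj_max = padj_max, log2fc_min = log2fc_min),
            class = "integration_thresholds")
}

.check_dm <- function(dm) {
  stopifnot(all(c("gene", "meth_diff", "q") %in% names(dm)))
  if (any(abs(dm$meth_diff) > 100)) stop("meth_diff must lie in [-100, 100]")
  if (any(dm$q < 0 | dm$q > 1)) stop("q must lie in [0, 1]")
  invisible(dm)
}

#' Filter differentially methylated regions
#'
#' Keeps records with |meth_diff| > `meth_diff_min` and q < `q_max`. When a
#' `coverage` column is present, records below 10 reads are dropped first
#' (the minimum-coverage convention of RRBS summarization).
#'
#' @param dm Tibble with `gene`, `meth_diff` (signed percentage points),
#'   `q`, optionally `region` (`"promoter"`/`"intragenic"`) and `coverage`.
#' @param thresholds An [integration_thresholds()].
#' @return The filtered tibble with a `direction` column (`"hypo"` for
#'   negative differences, `"hyper"` for positive) and attributes `n_hypo`,
#'   `n_hyper`.
#' @export
filter_dm <- function(dm, thresholds = integration_thresholds()) {
  dm <- .check_dm(tibble::as_tibble(dm))
  if ("coverage" %in% names(dm)) dm <- dm[dm$coverage >= 10, , drop = FALSE]
  keep <- abs(dm$meth_diff) > thresholds$meth_diff_min & dm$q < thresholds$q_max
  out <- dm[keep, , drop = FALSE]
  out$direction <- ifelse(out$meth_diff < 0, "hypo", "hyper")
  attr(out, "n_hypo") <- sum(out$direction == "hypo")
  attr(out, "n_hyper") <- sum(out$direction == "hyper")
  out
}

#' Filter differentially expressed genes
#'
#' Keeps records with padj < `padj_max` and |log2fc| >= `log2fc_min`
#' (boundary inclusive).
#'
#' @param deg Tibble with `gene`, `log2fc`, `padj` (a `fold_change` column
#'   is added as `2^log2fc` if absent).
#' @param thresholds An [integration_thresholds()].
#' @return The filtered tibble.
#' @export
filter_deg <- function(deg, thresholds = integration_thresholds()) {
  deg <- tibble::as_tibble(deg)
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(deg)))
  if (any(deg$padj < 0 | deg$padj > 1)) stop("padj must lie in [0, 1]")
  if (!"fold_change" %in% names(deg)) deg$fold_change <- 2^deg$log2fc
  if (any(abs(deg$fold_change - 2^deg$log2fc) > 1e-9))
    stop("fold_change column is inconsistent with log2fc")
  deg[deg$padj < thresholds$padj_max &
        abs(deg$log2fc) >= thresholds$log2fc_min, , drop = FALSE]
}

#' Integrate differential methylation with differential expression
#'
#' Inner join of filtered methylation and expression records on `gene`,
#' classifying each gene by the direction pair: `hypo_up` (decreased
#' methylation, increased expression) and `hyper_down` (increased
#' methylation, decreased expression) are the inverse associations of
#' interest; everything else is `concordant`. Output is sorted by
#' decreasing |meth_diff|.
#'
#' @param dm Output of [filter_dm()].
#' @param deg Output of [filter_deg()].
#' @return Tibble `gene`, `meth_diff`, `q`, `fold_change`, `log2fc`,
#'   `padj`, `class`.
#' @export
integrate_meth_expr <- function(dm, deg) {
  if (anyDuplicated(dm$gene))
    stop("duplicate gene rows in the methylation table: ",
         paste(unique(dm$gene[duplicated(dm$gene)]), collapse = ", "))
  if (anyDuplicated(deg$gene))
    stop("duplicate gene rows in the expression table: ",
         paste(unique(deg$gene[duplicated(deg$gene)]), collapse = ", "))
  joined <- dplyr::inner_join(
    dm[, intersect(c("gene", "region", "meth_diff", "q"), names(dm))],
    deg[, c("gene", "log2fc", "fold_change", "padj")], by = "gene")
  joined$class <- ifelse(joined$meth_diff < 0 & joined$fold_change > 1,
                         "hypo_up",
                         ifelse(joined$meth_diff > 0 & joined$fold_change < 1,
                                "hyper_down", "concordant"))
  dplyr::arrange(joined, dplyr::desc(abs(.data$meth_diff)))
}
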