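# Consensome building, high-confidence transcriptional target (HCT) sets,
# and the hypergeometric intersection footprint analysis, plus the
# thermoregulatory-node enrichment test.

#' Build a consensome for one signaling node
#'
#' Genes are scored by their mean peak strength across the node's datasets
#' and organized into percentiles: `percentile = 100 * rank / n_genes` with
#' max-rank tie handling, so tied genes share the best (highest) percentile.
#' Genes strictly above `hct_percentile` form the node's high confidence
#' transcriptional targets (the top 5 percent at the default 95).
#'
#' @param scores Tibble with columns `gene`, `score`, and optionally
#'   `dataset` (scores are averaged per gene across datasets).
#' @param hct_percentile HCT cutoff percentile (default 95).
#' @return A `consensome` tibble: `gene`, `score`, `percentile`, `hct`,
#'   sorted by decreasing score.
#' @export
build_consensome <- function(scores, hct_percentile = 95) {
  stopifnot(all(c("gene", "score") %in% names(scores)))
  if (nrow(scores) == 0) stop("empty gene list")
  agg <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(scores), .data$gene),
                          score = mean(.data$score), .groups = "drop")
  n <- nrow(agg)
  rk <- rank(agg$score, ties.method = "max")
  agg$percentile <- 100 * rk / n
  agg$hct <- agg$percentile > hct_percentile
  out <- dplyr::arrange(agg, dplyr::desc(.data$score), .data$gene)
  class(out) <- c("consensome", class(out))
  out
}

# Hypergeometric upper tail: P(overlap >= k) for a gene set of size n drawn
# from a universe of N containing K marked genes.
.hyper_upper <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' HCT intersection analysis of a gene set against node consensomes
#'
#' For each node, the overlap k between the query gene set (size n) and the
#' node's HCTs (size K) within the gene universe (size N) is tested with
#' the hypergeometric upper tail; p-values are BH-adjusted across nodes to
#' q-values. The odds ratio uses the Haldane-Anscombe 0.5 correction when
#' any contingency cell is zero, so log-OR stays finite.
#'
#' @param gene_set Character vector of query genes (case-folded symbols).
#' @param consensomes Named list of `consensome` tibbles (one per node), or
#'   a single tibble with a `node` column plus `gene`, `percentile`.
#' @param universe Character vector of universe genes. Defaults to the union
#'   of all genes scored in any consensome. Query genes outside the universe
#'   are dropped with a warning.
#' @param hct_percentile HCT cutoff (strictly-above, default 95).
#' @return Tibble per node: `node`, `k`, `n`, `K`, `N`, `odds_ratio`, `p`,
#'   `q`, sorted by q then p.
#' @export
hct_intersection <- function(gene_set, consensomes, universe = NULL,
                             hct_percentile = 95) {
  gene_set <- tolower(unique(gene_set))
  if (inherits(consensomes, "data.frame")) {
    stopifnot("node" %in% names(consensomes))
    consensomes <- split(consensomes[setdiff(names(consensomes), "node")],
                         consensomes$node)
  }
  hcts <- lapply(consensomes, function(cs) {
    tolower(cs$gene[cs$percentile > hct_percentile])
  })
  all_genes <- tolower(unique(unlist(lapply(consensomes, function(cs) cs$gene))))
  if (is.null(universe)) universe <- all_genes else universe <- tolower(unique(universe))
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "")
    gene_set <- intersect(gene_set, universe)
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(hcts), function(node) {
    hct <- intersect(hcts[[node]], universe)
    K <- length(hct)
    k <- length(intersect(gene_set, hct))
    cells <- c(k, n - k, K - k, N - K - n + k)
    if (any(cells == 0)) cells <- cells + 0.5
    tibble::tibble(node = node, k = k, n = n, K = K, N = N,
                   odds_ratio = (cells[1] / cells[2]) / (cells[3] / cells[4]),
                   p = .hyper_upper(k, K, n, N))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  dplyr::arrange(out, .data$q, .data$p, .data$node)
}

#' Enrichment of thermoregulatory nodes among top-ranked footprint nodes
#'
#' Tests whether nodes annotated to thermoregulatory-deficiency phenotypes
#' concentrate among the nodes with the strongest transcriptional
#' footprints: hypergeometric upper-tail p for the count of thermo nodes in
#' the top fraction of the ranked node list, against a universe of
#' `universe_size` nodes (default 691) containing the thermo set (default
#' size 15).
#'
#' @param ranked_nodes Character vector of node ids, strongest footprint
#'   first; must be drawn from the universe.
#' @param thermo_nodes Character vector of thermoregulatory node ids.
#' @param top_fraction Fraction of `ranked_nodes` regarded as top-ranked
#'   (in (0, 1]).
#' @param universe_size Total number of unique nodes in the analysis.
#' @return List with `k` (thermo nodes in the top set), `n` (top-set size),
#'   `K` (thermo set size), `N` (universe), and `p`.
#' @export
thermo_enrichment <- function(ranked_nodes, thermo_nodes, top_fraction,
                              universe_size = 691) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (length(ranked_nodes) > universe_size)
    stop("ranked node list exceeds the universe size")
  n_top <- ceiling(top_fraction * length(ranked_nodes))
  top <- utils::head(ranked_nodes, n_top)
  K <- length(unique(thermo_nodes))
  k <- length(intersect(top, thermo_nodes))
  list(k = k, n = n_top, K = K, N = universe_size,
       p = .hyper_upper(k, K, n_top, universe_size))
}
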