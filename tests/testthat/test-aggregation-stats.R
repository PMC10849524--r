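# Abundance normalization, {} aggregation semantics, bulk metrics,
# pp/fold comparisons, and the FDR procedures.

test_that("normalization scales class intensities to percent and averages replicates", {
  base <- tibble::tibble(family = "H4", sample = "s1", condition = "TN",
                         tissue = "BAT")
  one <- dplyr::mutate(base, notation = "H4<>", replicate = 1,
                       class_intensity = 777, fraction = 1)
  out <- normalize_abundance(one)
  expect_equal(out$abundance, 100)
  two <- dplyr::bind_rows(
    dplyr::mutate(base, notation = "H4<>", replicate = 1,
                  class_intensity = 300, fraction = 1),
    dplyr::mutate(base, notation = "H4<K16ac>", replicate = 1,
                  class_intensity = 100, fraction = 1))
  out2 <- normalize_abundance(two)
  expect_equal(sort(out2$abundance), c(25, 75))
  reps <- dplyr::bind_rows(
    dplyr::mutate(base, notation = "H4<>", replicate = 1,
                  class_intensity = 40, fraction = 1),
    dplyr::mutate(base, notation = "H4<K16ac>", replicate = 1,
                  class_intensity = 60, fraction = 1),
    dplyr::mutate(base, notation = "H4<>", replicate = 2,
                  class_intensity = 60, fraction = 1),
    dplyr::mutate(base, notation = "H4<K16ac>", replicate = 2,
                  class_intensity = 40, fraction = 1))
  out3 <- normalize_abundance(reps)
  expect_equal(out3$abundance, c(50, 50))
})

test_that("zero-intensity samples are dropped with a warning", {
  quant <- tibble::tibble(family = "H4", notation = "H4<>",
                          sample = c("ok", "dead"), condition = "TN",
                          tissue = "BAT", replicate = 1,
                          class_intensity = c(10, 0), fraction = 1)
  expect_warning(out <- normalize_abundance(quant), "zero total intensity")
  expect_equal(out$sample, "ok")
})

test_that("discrete PTM sums follow the {} semantics", {
  tbl <- toy_table(c("H3.2<>" = 93, "H3.2<K9me2K27me1>" = 6,
                     "H3.2<K9me3>" = 1), family = "H3.2")
  expect_equal(discrete_ptm(tbl, "{K9me2/3}")$value, 7.0)
  expect_equal(discrete_ptm(tbl, "{}")$value, 100)     # empty query: everything
  expect_equal(discrete_ptm(tbl, "H3.2<K9me3>")$value, 1)  # exact <> query
  expect_error(discrete_ptm(tbl, "H4<K16ac>"), "family")
})

test_that("binary contains-queries equal brute-force filter-and-sum on random tables", {
  s <- ptm_schema("H3.2")
  e <- enumerate_proteoforms(s)
  withr::with_seed(41, {
    for (i in 1:5) {
      pick <- sample(nrow(e), 30)
      ab <- stats::rgamma(30, 1); ab <- 100 * ab / sum(ab)
      tbl <- toy_table(stats::setNames(ab, e$notation[pick]), family = "H3.2")
      got <- discrete_ptm(tbl, "{K27me3K36un}")$value
      brute <- sum(ab[e$K27[pick] == "me3" & e$K36[pick] == "un"])
      expect_equal(got, brute, tolerance = 1e-9)
      # {} of an exact set always >= <> of the same set
      note <- e$notation[pick[1]]
      q <- parse_notation(note)
      q$mode <- "contains"
      if (length(q$sites) > 0)
        expect_gte(discrete_ptm(tbl, q)$value,
                   discrete_ptm(tbl, note)$value - 1e-12)
    }
  })
})

test_that("K9 state partition conserves 100 percent per sample", {
  s <- ptm_schema("H3.2")
  e <- enumerate_proteoforms(s)
  withr::with_seed(42, {
    pick <- sample(nrow(e), 40)
    ab <- stats::rgamma(40, 1); ab <- 100 * ab / sum(ab)
    tbl <- toy_table(stats::setNames(ab, e$notation[pick]), family = "H3.2")
    states <- c("un", "ac", "me1", "me2", "me3")
    total <- sum(vapply(states, function(st)
      discrete_ptm(tbl, paste0("{K9", st, "}"))$value, numeric(1)))
    expect_equal(total, 100, tolerance = 1e-9)
    # adding a constraint can only shrink a contains-query
    expect_lte(discrete_ptm(tbl, "{K9me2K36me1}")$value,
               discrete_ptm(tbl, "{K9me2}")$value + 1e-12)
  })
})

test_that("bulk metrics count side-chain acetyls and methyls per molecule", {
  tbl <- toy_table(c("H4<>" = 50, "H4<K16ac>" = 30, "H4<K8acK16ac>" = 20))
  bm <- bulk_metrics(tbl)
  expect_equal(bm$percent_acetylated, 50)     # N-terminal ac never counts
  expect_equal(bm$acetyls_per_molecule, 0.7)  # (30*1 + 20*2)/100
  expect_equal(bm$percent_methylated, 0)
  bm2 <- bulk_metrics(toy_table(c("H4<K20me2>" = 100)))
  expect_equal(bm2$percent_methylated, 100)
  expect_equal(bm2$methyls_per_molecule, 2.0)  # me2 counts two methyl groups
  bm3 <- bulk_metrics(toy_table(c("H4<>" = 100)))
  expect_equal(unlist(bm3[, 4:7], use.names = FALSE), rep(0, 4))
  # identity: percent_acetylated == 100 - abundance(zero side-chain ac)
  expect_equal(bm$percent_acetylated, 100 - 50)
})

test_that("comparisons report the printed worked pp and fold changes", {
  # two identical observations per group pin the group means
  d <- tibble::tibble(value = c(6.0, 6.0, 1.7, 1.7),
                      group = c("BAT", "BAT", "liver", "liver"))
  cmp <- compare_groups(d, metric = "H3.2<K9me2K27me1>")
  expect_equal(cmp$pp_change, 4.3)
  d2 <- tibble::tibble(value = c(36, 36, 39.4, 39.4),
                       group = c("BAT", "BAT", "liver", "liver"))
  cmp2 <- compare_groups(d2, metric = "H4<K20me2>")
  expect_equal(round(cmp2$fold_change, 2), 0.91)
  expect_equal(cmp2$pp_change, -3.4)
})

test_that("identical groups give pp 0, fold 1, p 1", {
  d <- tibble::tibble(value = c(5, 6, 5, 6), group = c("a", "a", "b", "b"))
  cmp <- compare_groups(d)
  expect_equal(cmp$pp_change, 0)
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)
})

test_that("three groups get ANOVA with Tukey-adjusted pairwise p-values", {
  withr::with_seed(8, {
    d <- tibble::tibble(value = c(rnorm(4, 10), rnorm(4, 10), rnorm(4, 20)),
                        group = rep(c("TN", "RT", "SC"), each = 4))
    cmp <- compare_groups(d)
    expect_equal(nrow(cmp), 3)
    expect_true(all(!is.na(cmp$p)))
    expect_true(all(cmp$anova_p == cmp$anova_p[1]))
    ref <- stats::TukeyHSD(stats::aov(value ~ group,
                                      data = transform(d, group = factor(group))))
    expect_equal(sort(cmp$p), sort(unname(ref$group[, "p adj"])),
                 tolerance = 1e-9)
  })
})

test_that("groups of one observation yield descriptives without statistics", {
  d <- tibble::tibble(value = c(5, 7), group = c("a", "b"))
  cmp <- compare_groups(d)
  expect_true(is.na(cmp$p))
  expect_equal(cmp$pp_change, -2)
})

test_that("volcano significance needs both p and fold beyond their cutoffs", {
  withr::with_seed(9, {
    a <- rnorm(6, 10, 0.1); b <- rnorm(6, 12, 0.1)   # fold 1.2: significant p only
    cmp <- compare_groups(tibble::tibble(value = c(a, b),
                                         group = rep(c("x", "y"), each = 6)))
    expect_lt(cmp$p, 0.05)
    expect_false(cmp$significant)
    a2 <- rnorm(6, 10, 0.1); b2 <- rnorm(6, 16, 0.1)  # fold 1.6 and small p
    cmp2 <- compare_groups(tibble::tibble(value = c(b2, a2),
                                          group = rep(c("x", "y"), each = 6)))
    expect_true(cmp2$significant)
  })
})

test_that("compare_metric wires discrete queries into group comparisons", {
  tbl <- dplyr::bind_rows(
    toy_table(c("H3.2<>" = 94, "H3.2<K9me2K27me1>" = 6), family = "H3.2",
              sample = "b1", tissue = "BAT"),
    toy_table(c("H3.2<>" = 94, "H3.2<K9me2K27me1>" = 6), family = "H3.2",
              sample = "b2", tissue = "BAT"),
    toy_table(c("H3.2<>" = 98.3, "H3.2<K9me2K27me1>" = 1.7), family = "H3.2",
              sample = "l1", tissue = "liver"),
    toy_table(c("H3.2<>" = 98.3, "H3.2<K9me2K27me1>" = 1.7), family = "H3.2",
              sample = "l2", tissue = "liver"))
  cmp <- compare_metric(tbl, "H3.2<K9me2K27me1>", by = "tissue")
  expect_equal(cmp$pp_change, 4.3)
  expect_equal(cmp$metric, "H3.2<K9me2K27me1>")
})

test_that("BH adjustment matches the hand step-up and dominates p", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(55, {
    for (i in 1:20) {
      p <- stats::runif(sample(3:30, 1))
      q <- bh_adjust(p)
      expect_true(all(q >= p - 1e-12))
      expect_equal(q, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-stage step-up flags behave at the extremes", {
  expect_equal(fdr_two_stage(rep(1, 8))$n_discoveries, 0L)
  expect_equal(fdr_two_stage(rep(0.001, 10))$n_discoveries, 10L)
  res <- fdr_two_stage(c(0.001, 0.002, 0.9, 0.95))
  # adjusted values are consistent with the flags at the chosen level
  expect_equal(res$reject, res$q <= 0.05)
  # flags are monotone in sorted p: the rejected set is the k smallest
  p <- c(0.5, 0.001, 0.04, 0.8, 0.002)
  r <- fdr_two_stage(p)
  k <- r$n_discoveries
  expect_setequal(which(r$reject), order(p)[seq_len(k)])
})

test_that("two-stage step-up matches the frozen independent reference", {
  ref <- utils::read.delim(test_path("fixtures", "bky_reference.tsv"))
  pv <- pvalue_battery(nrow(ref))
  mine <- vapply(pv, function(p) fdr_two_stage(p, 0.05)$n_discoveries,
                 integer(1))
  expect_equal(lengths(pv), ref$m)
  expect_equal(mine, ref$n_reject)
})

test_that("the DEG log2 fold-change cutoff is 0.263 for a 20 percent change", {
  expect_equal(deg_log2fc_cutoff(20), 0.263)
  expect_equal(deg_log2fc_cutoff(50), round(log2(1.5), 3))
})
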