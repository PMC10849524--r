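# Seeded generators for every input the pipeline consumes: ground-truth
# proteoform mixtures and their MS1/MS2 spectra, consensome score tables
# with a planted footprint, and methylation/expression tables with planted
# inverse associations. All draws are fixed by (seed, config).

#' Simulation configuration
#'
#' Defaults emulate the study design: three housing conditions (TN, RT,
#' SC), 4 biological animals per group, two technical replicates per
#' sample, lognormal multiplicative intensity noise at 10 percent CV, and
#' 80 percent fragment-ladder coverage. Charge envelopes are discretized
#' Gaussians per family, centered so peaks land inside the acquisition scan
#' ranges (H4: z around 13; H3.2 tail: z around 9).
#'
#' @param seed Integer seed fixing all downstream draws.
#' @param family `"H4"` or `"H3.2"`.
#' @param n_active Number of proteoforms with nonzero abundance.
#' @param dirichlet Dirichlet concentration of the base abundance draw.
#' @param biological_cv Between-animal lognormal CV on abundances.
#' @param noise_cv Multiplicative CV of peak intensities.
#' @param coverage Fraction of the c/z fragment ladder observed, in (0, 1].
#' @param charge_center,charge_spread Charge envelope (defaults by family).
#' @param tissues,conditions Group design.
#' @param n_biological Animals per (tissue, condition) group.
#' @param n_technical Technical replicates per sample (averaged downstream).
#' @param total_intensity MS1 intensity of the full family envelope.
#' @param effect Optional planted group effect:
#'   `list(query =, condition =, delta_pp =)` shifts the summed abundance of
#'   the query by `delta_pp` percentage points in that condition.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, family = c("H4", "H3.2"), n_active = 12L,
                       dirichlet = 1, biological_cv = 0.05, noise_cv = 0.1,
                       coverage = 0.8, charge_center = NULL,
                       charge_spread = NULL, tissues = "BAT",
                       conditions = c("TN", "RT", "SC"), n_biological = 4L,
                       n_technical = 2L, total_intensity = 1e6,
                       effect = NULL) {
  family <- match.arg(family)
  if (is.null(charge_center)) charge_center <- if (family == "H4") 13 else 9
  if (is.null(charge_spread)) charge_spread <- if (family == "H4") 1.5 else 0.5
  stopifnot(noise_cv >= 0, coverage > 0, coverage <= 1, n_active >= 1,
            n_technical >= 1, n_biological >= 1)
  structure(list(seed = as.integer(seed), family = family,
                 n_active = as.integer(n_active), dirichlet = dirichlet,
                 biological_cv = biological_cv, noise_cv = noise_cv,
                 coverage = coverage, charge_center = charge_center,
                 charge_spread = charge_spread, tissues = tissues,
                 conditions = conditions,
                 n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 total_intensity = total_intensity, effect = effect),
            class = "sim_config")
}

.lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Simulate a ground-truth proteoform mixture
#'
#' Draws a sparse Dirichlet abundance profile over `n_active` proteoforms
#' of the family's schema, applies an optional planted group effect, and
#' jitters per-animal abundances with a small lognormal factor. Technical
#' replicates share the animal's truth (they differ only through
#' measurement noise added by [simulate_spectra()]).
#'
#' @param schema A [ptm_schema()] matching `config$family`.
#' @param config A [sim_config()].
#' @return List with `truth` (tibble: family, notation, sample, condition,
#'   tissue, abundance; abundances sum to 100 per sample), `manifest`
#'   (a [run_manifest()] with one row per technical replicate), and
#'   `active` (the active subset of the enumeration, with site columns).
#' @export
simulate_mixture <- function(schema, config = sim_config()) {
  stopifnot(inherits(schema, "ptm_schema"), schema$family == config$family)
  enum <- enumerate_proteoforms(schema)
  if (config$n_active > nrow(enum))
    stop("n_active exceeds the proteoform space (", nrow(enum), ")")
  withr::with_seed(config$seed, {
    active_idx <- sort(sample.int(nrow(enum), config$n_active))
    active <- enum[active_idx, , drop = FALSE]
    base <- stats::rgamma(config$n_active, shape = config$dirichlet)
    base <- 100 * base / sum(base)
    design <- expand.grid(animal = seq_len(config$n_biological),
                          condition = config$conditions,
                          tissue = config$tissues,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_%s_%d", design$tissue, design$condition,
                             design$animal)
    match_eff <- if (!is.null(config$effect))
      query_matches(config$effect$query, active, schema) else NULL
    rows <- lapply(seq_len(nrow(design)), function(i) {
      ab <- base * .lognorm_noise(config$n_active, config$biological_cv)
      ab <- 100 * ab / sum(ab)
      if (!is.null(match_eff) &&
          design$condition[i] == config$effect$condition) {
        cur <- sum(ab[match_eff])
        target <- min(max(cur + config$effect$delta_pp, 0), 100)
        if (cur > 0 && cur < 100) {
          ab[match_eff] <- ab[match_eff] * target / cur
          ab[!match_eff] <- ab[!match_eff] * (100 - target) / (100 - cur)
        }
      }
      tibble::tibble(family = schema$family, notation = active$notation,
                     sample = design$sample[i],
                     condition = design$condition[i],
                     tissue = design$tissue[i], abundance = ab)
    })
    truth <- dplyr::bind_rows(rows)
    manifest <- run_manifest(tidyr::crossing(
      design[, c("sample", "condition", "tissue")],
      replicate = seq_len(config$n_technical)))
    list(truth = truth, manifest = manifest, active = active)
  })
}

.charge_grid <- function(config) {
  lo <- max(1L, floor(config$charge_center - 3 * config$charge_spread))
  hi <- ceiling(config$charge_center + 3 * config$charge_spread)
  z <- lo:hi
  w <- stats::dnorm(z, config$charge_center, config$charge_spread)
  stats::setNames(w / sum(w), z)
}

#' Simulate MS1/MS2 spectra from a ground-truth mixture
#'
#' MS1 peaks are placed at `neutral_to_mz` over the discretized Gaussian
#' charge envelope (intensity proportional to abundance times envelope
#' weight, clipped to the family scan range). Per isobaric class one MS2
#' spectrum is produced whose merged c/z fragment intensities are the
#' linear mixture of the co-isolated members' fractions, thinned to the
#' configured ladder coverage and multiplied by lognormal noise.
#'
#' @param mixture Output of [simulate_mixture()].
#' @param schema The matching [ptm_schema()].
#' @param config The same [sim_config()].
#' @param msconfig An [ms_config()].
#' @return List of runs; each run is a list with `sample`, `condition`,
#'   `tissue`, `replicate`, and `spectra` (MS1 first, then one MS2 per
#'   class).
#' @export
simulate_spectra <- function(mixture, schema, config = sim_config(),
                             msconfig = ms_config()) {
  enum <- proteoform_masses(enumerate_proteoforms(schema), schema,
                            scale = msconfig$mass_scale)
  cls <- isobaric_classes(enum, msconfig)
  members <- cls$members
  truth <- mixture$truth
  manifest <- mixture$manifest
  rng <- .scan_range(msconfig, schema$family)
  zw <- .charge_grid(config)
  zs <- as.integer(names(zw))
  bb <- histone_backbone(schema$backbone)
  frag_cache <- new.env(parent = emptyenv())
  frags_of <- function(notation) {
    if (is.null(frag_cache[[notation]])) {
      i <- match(notation, members$notation)
      st <- .row_states(members, schema, i)
      fl <- etd_fragments(bb, st, scale = "monoisotopic")
      frag_cache[[notation]] <- c(fl$c, fl$z)
    }
    frag_cache[[notation]]
  }
  withr::with_seed(config$seed + 1L, {
    runs <- lapply(seq_len(nrow(manifest)), function(ri) {
      smp <- manifest$sample[ri]
      rep_i <- manifest$replicate[ri]
      tr <- truth[truth$sample == smp & truth$abundance > 0, , drop = FALSE]
      info <- members[match(tr$notation, members$notation), , drop = FALSE]
      # --- MS1 ---
      grid <- tidyr::crossing(idx = seq_len(nrow(tr)), z = zs)
      grid$mass <- info$mass[grid$idx]
      grid$mz <- grid$mass / grid$z + msconfig$proton_da
      grid$intensity <- config$total_intensity *
        tr$abundance[grid$idx] / 100 * zw[as.character(grid$z)] *
        .lognorm_noise(nrow(grid), config$noise_cv)
      grid <- grid[grid$mz >= rng[1] & grid$mz <= rng[2], , drop = FALSE]
      grid <- grid[order(grid$mz), , drop = FALSE]
      ms1 <- spectrum_peaklist("MS1", grid$mz, grid$intensity,
                               charge = grid$z,
                               scan_id = sprintf("%s_r%d_ms1", smp, rep_i),
                               family = schema$family)
      # --- MS2, one per occupied isobaric class ---
      ms2 <- lapply(sort(unique(info$class_id)), function(cid) {
        in_cls <- info$class_id == cid
        fr <- tr$abundance[in_cls] / sum(tr$abundance[in_cls])
        notes <- tr$notation[in_cls]
        fm <- unlist(lapply(notes, frags_of))
        fw <- rep(fr, each = length(frags_of(notes[1])))
        merged <- .merge_observed(fm, fw, msconfig$frag_tol_ppm)
        seen <- stats::runif(nrow(merged)) <= config$coverage
        merged <- merged[seen & merged$intensity > 0, , drop = FALSE]
        inten <- 1e4 * merged$intensity *
          .lognorm_noise(nrow(merged), config$noise_cv)
        cmass <- cls$classes$class_mass[cls$classes$class_id == cid]
        zc <- as.integer(round(config$charge_center))
        spectrum_peaklist("MS2", merged$mass + msconfig$proton_da, inten,
                          precursor = list(mz = cmass / zc + msconfig$proton_da,
                                           charge = zc,
                                           window_da = msconfig$ms1_window_da),
                          scan_id = sprintf("%s_r%d_ms2_c%d", smp, rep_i, cid),
                          family = schema$family)
      })
      list(sample = smp, condition = manifest$condition[ri],
           tissue = manifest$tissue[ri], replicate = rep_i,
           spectra = c(list(ms1), ms2))
    })
    runs
  })
}

#' Quantify simulated or imported runs through the full pipeline
#'
#' For each run: MS1 peaks are assigned to isobaric classes
#' ([assign_precursors()]); each MS2 spectrum is matched against its
#' precursor class's candidate proteoforms ([match_fragments()]) and
#' apportioned ([apportion()]); class intensity times fraction gives the
#' per-proteoform quantitation fed to [normalize_abundance()].
#'
#' @param runs List of runs as produced by [simulate_spectra()].
#' @param schema The family [ptm_schema()].
#' @param msconfig An [ms_config()].
#' @return Tibble ready for [normalize_abundance()]: one row per
#'   (run, proteoform-with-support).
#' @export
quantify_runs <- function(runs, schema, msconfig = ms_config()) {
  enum <- proteoform_masses(enumerate_proteoforms(schema), schema,
                            scale = msconfig$mass_scale)
  cls <- isobaric_classes(enum, msconfig)
  half <- msconfig$ms1_window_da / 2
  out <- lapply(runs, function(run) {
    ms1 <- Filter(function(s) s$level == "MS1", run$spectra)
    ms2 <- Filter(function(s) s$level == "MS2", run$spectra)
    obs <- assign_precursors(ms1, cls, msconfig, family = schema$family)$observations
    if (nrow(obs) == 0) return(NULL)
    rows <- lapply(ms2, function(sp) {
      prec_neutral <- mz_to_neutral(sp$precursor$mz, sp$precursor$charge)
      d <- abs(cls$classes$class_mass - prec_neutral)
      j <- which.min(d)
      if (d[j] > half) return(NULL)
      cid <- cls$classes$class_id[j]
      if (!cid %in% obs$class_id) return(NULL)
      cand <- cls$members[cls$members$class_id == cid, , drop = FALSE]
      ap <- apportion(match_fragments(sp, cand, schema, msconfig))
      tibble::tibble(family = schema$family,
                     notation = names(ap$fractions),
                     sample = run$sample, condition = run$condition,
                     tissue = run$tissue, replicate = run$replicate,
                     class_intensity = obs$intensity[obs$class_id == cid],
                     fraction = unname(ap$fractions),
                     ambiguous = ap$ambiguous)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Simulate, quantify and normalize in one call
#'
#' @param schema A [ptm_schema()].
#' @param config A [sim_config()].
#' @param msconfig An [ms_config()].
#' @return List with `truth`, `manifest`, and `recovered` (the normalized
#'   abundance table produced by the full pipeline).
#' @export
run_pipeline <- function(schema, config = sim_config(),
                         msconfig = ms_config()) {
  mix <- simulate_mixture(schema, config)
  runs <- simulate_spectra(mix, schema, config, msconfig)
  quant <- quantify_runs(runs, schema, msconfig)
  recovered <- normalize_abundance(quant)
  list(truth = mix$truth, manifest = mix$manifest, recovered = recovered)
}

#' Simulate consensome score tables with one planted footprint node
#'
#' Every node scores every gene across `n_datasets` datasets with
#' independent exponential peak strengths. The query gene set draws
#' `overlap_rate` of its members from the planted node's HCTs (top 5
#' percent by mean score) and the rest from the remaining universe.
#'
#' @param n_nodes,n_genes,n_datasets Universe dimensions.
#' @param planted_node Name of the planted node (must be among the nodes).
#' @param overlap_rate Fraction of the gene set drawn from the planted HCT.
#' @param gene_set_size Query set size.
#' @param seed Integer seed.
#' @return List with `scores` (tibble node, dataset, gene, score),
#'   `gene_set`, `universe`, `planted_node`.
#' @export
simulate_consensomes <- function(n_nodes = 50, n_genes = 2000,
                                 planted_node = "node01",
                                 overlap_rate = 0.8, gene_set_size = 100,
                                 n_datasets = 3, seed = 1L) {
  nodes <- sprintf("node%02d", seq_len(n_nodes))
  stopifnot(planted_node %in% nodes, overlap_rate >= 0, overlap_rate <= 1)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    scores <- tidyr::crossing(node = nodes, dataset = seq_len(n_datasets),
                              gene = genes)
    scores$score <- stats::rexp(nrow(scores))
    planted <- build_consensome(scores[scores$node == planted_node,
                                       c("gene", "score")])
    hct <- planted$gene[planted$hct]
    n_in <- round(overlap_rate * gene_set_size)
    gene_set <- c(sample(hct, min(n_in, length(hct))),
                  sample(setdiff(genes, hct), gene_set_size - min(n_in, length(hct))))
    list(scores = scores, gene_set = gene_set, universe = genes,
         planted_node = planted_node)
  })
}

#' Simulate methylation/expression tables with planted inverse associations
#'
#' Plants `n_inverse` genes with an inverse promoter-methylation /
#' expression association (half hypomethylated-up, half
#' hypermethylated-down), `n_concordant` genes passing both filters with
#' concordant directions, and nulls failing both filters. Filters are
#' deterministic, so the planted classes are recovered exactly by
#' [filter_dm()] + [filter_deg()] + [integrate_meth_expr()].
#'
#' @param n_genes Total genes.
#' @param n_inverse Planted inverse associations.
#' @param n_concordant Planted concordant associations.
#' @param seed Integer seed.
#' @return List with `dm`, `deg`, and `truth` (gene, class).
#' @export
simulate_methexpr <- function(n_genes = 500, n_inverse = 20,
                              n_concordant = 5, seed = 1L) {
  stopifnot(n_inverse + n_concordant <= n_genes)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  withr::with_seed(seed, {
    genes <- sample(genes)
    cl <- rep("null", n_genes)
    cl[seq_len(n_inverse)] <- rep(c("hypo_up", "hyper_down"),
                                  length.out = n_inverse)
    cl[n_inverse + seq_len(n_concordant)] <- rep(c("hypo_down", "hyper_up"),
                                                 length.out = n_concordant)
    md_sign <- ifelse(grepl("^hypo", cl), -1, 1)
    md <- md_sign * stats::runif(n_genes, 5.5, 35)
    q <- stats::runif(n_genes, 1e-8, 0.04)
    fc_sign <- ifelse(grepl("up$", cl), 1, -1)
    lfc <- fc_sign * stats::runif(n_genes, 0.3, 1.5)
    padj <- stats::runif(n_genes, 1e-10, 0.04)
    null <- cl == "null"
    # nulls fail both filters outright
    q[null] <- stats::runif(sum(null), 0.06, 1)
    padj[null] <- stats::runif(sum(null), 0.06, 1)
    truth_class <- ifelse(cl %in% c("hypo_up", "hyper_down"), cl,
                          ifelse(null, "null", "concordant"))
    list(dm = tibble::tibble(gene = genes, region = "promoter",
                             meth_diff = md, q = q),
         deg = tibble::tibble(gene = genes, log2fc = lfc, padj = padj),
         truth = tibble::tibble(gene = genes, class = truth_class))
  })
}
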