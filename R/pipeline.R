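pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    simulate = list(
      n_samples = 200, n_modules = 5, genes_per_module = 40,
      n_background_genes = 100, loading_range = c(0.8, 0.8),
      count_dispersion = 0.1, n_batches = 2, batch_shift_sd = 0.3,
      bone_gene_fraction = 0.3, n_decoy_leads = 5
    ),
    preprocess = list(
      min_reads = 6, min_tpm = 0.1, min_fraction = 0.2,
      adjust_for = "batch", protect = "sex"
    ),
    modules = list(
      power = 4, min_module_size = 30, merge_height = 0.15,
      cut_height = NULL, network_label = "combined"
    ),
    bn = list(alpha = 0.05, max_sepset = 3, max_iterations = 500,
              ridge = 1e-8, max_genes = 1000),
    ban = list(steps = 3, p_threshold = 0.05),
    coloc = list(
      window = 2e5, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
      prior_effect_sd = 0.15, pph4_threshold = 0.75,
      n_snps = 100, ld_rho = 0.9, n1 = 5000, n2 = 5000,
      var_explained = 0.01
    ),
    integrate = list(proximity_bp = 1e6, n_perm = 200, locus_half_width = 25e4)
  )
}

#' Pipeline configuration
#'
#' Builds the nested parameter list driving [run_pipeline()], starting from
#' the package defaults (power 4, minimum module size 30, merge height
#' 0.15, neighborhood step 3, BAN p <= 0.05, coloc window 200 kb,
#' proximity 1 Mbp, PPH4 >= 0.75) and overriding with whatever blocks are
#' supplied. Unknown keys anywhere in the structure are rejected.
#'
#' @param ... Named overrides: top-level scalars (`seed`, `out_dir`) or
#'   stage blocks (`simulate`, `preprocess`, `modules`, `bn`, `ban`,
#'   `coloc`, `integrate`) given as named lists.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(bad, collapse = ", ")))
  }
  for (key in names(override)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      inner_bad <- setdiff(names(override[[key]]), names(defaults[[key]]))
      if (length(inner_bad)) {
        abort(paste0("unknown key(s) in `", key, "` block: ",
                     paste(inner_bad, collapse = ", ")))
      }
      defaults[[key]][names(override[[key]])] <- override[[key]]
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

subset_counts <- function(cm, genes) {
  count_matrix(cm$counts[genes, , drop = FALSE],
               if (!is.null(cm$tpm)) cm$tpm[genes, , drop = FALSE])
}

# lead-SNP catalog for a simulated study: one lead at each driver gene's
# midpoint plus decoy leads at random background-gene midpoints
simulate_leads <- function(study, n_decoy, seed) {
  gt <- study$gene_table
  drivers <- study$truth$driver_genes
  mid <- function(g) {
    i <- match(g, gt$gene_id)
    floor((gt$start[i] + gt$end[i]) / 2)
  }
  lead_genes <- drivers
  background <- gt$gene_id[study$truth$module_of_gene[gt$gene_id] ==
                             "background"]
  if (n_decoy > 0) {
    decoys <- with_seed(seed, sample(background, min(n_decoy,
                                                     length(background))))
    lead_genes <- c(lead_genes, decoys)
  }
  i <- match(lead_genes, gt$gene_id)
  tibble::tibble(
    snp_id = sprintf("lead%03d", seq_along(lead_genes)),
    chrom = gt$chrom[i],
    pos = vapply(lead_genes, mid, numeric(1)),
    source_gene = lead_genes
  )
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> preprocess -> module detection -> per-module
#' Bayesian network learning -> BAN analysis -> colocalization of
#' GWAS-proximal BANs -> candidate integration, entirely from one seeded
#' configuration, and assembles a machine-readable report. Identical
#' config + seed gives identical results and report.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `netban_run` with the per-stage artifacts
#'   (`study`, `partition`, `networks`, `ban`, `coloc`, `candidates`,
#'   `proximity`, `overlap_null`, `enrichment`) and `report` (the list
#'   serialized to `report.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  seed <- config$seed

  # --- simulate ------------------------------------------------------------
  sim <- config$simulate
  scfg <- sim_config(
    n_samples = sim$n_samples, n_modules = sim$n_modules,
    genes_per_module = sim$genes_per_module,
    n_background_genes = sim$n_background_genes,
    loading_range = sim$loading_range,
    count_dispersion = sim$count_dispersion, n_batches = sim$n_batches,
    batch_shift_sd = sim$batch_shift_sd,
    bone_gene_fraction = sim$bone_gene_fraction,
    seed = derive_seed(seed, 1)
  )
  study <- gen_expression_study(scfg)
  leads <- simulate_leads(study, sim$n_decoy_leads, derive_seed(seed, 2))

  # --- preprocess ----------------------------------------------------------
  pp <- config$preprocess
  expressed <- filter_expressed(study$counts, pp$min_reads, pp$min_tpm,
                                pp$min_fraction)
  cm1 <- subset_counts(study$counts, expressed)
  net_genes <- filter_network_genes(cm1, study$gene_table)
  expr <- normalize_adjust(subset_counts(study$counts, net_genes),
                           study$covariates,
                           adjust_for = pp$adjust_for, protect = pp$protect)

  # --- modules -------------------------------------------------------------
  mo <- config$modules
  adj <- signed_adjacency(expr, power = mo$power)
  tom <- tom_similarity(adj)
  partition <- detect_modules(tom, expr,
                              min_module_size = mo$min_module_size,
                              merge_height = mo$merge_height,
                              cut_height = mo$cut_height,
                              network_label = mo$network_label)
  truth_mod <- study$truth$module_of_gene[net_genes]
  ari <- mclust::adjustedRandIndex(truth_mod,
                                   partition$module_of_gene[net_genes])

  # --- bayesian networks ---------------------------------------------------
  bnc <- bn_config(alpha = config$bn$alpha, max_sepset = config$bn$max_sepset,
                   max_iterations = config$bn$max_iterations,
                   ridge = config$bn$ridge, max_genes = config$bn$max_genes)
  mods <- setdiff(unique(partition$module_of_gene), "unassigned")
  networks <- lapply(setNames(mods, mods), function(m) {
    genes <- names(partition$module_of_gene)[partition$module_of_gene == m]
    dat <- expr[genes, , drop = FALSE]
    hill_climb(dat, mmpc_skeleton(dat, bnc), bnc)
  })
  networks <- list(networks)
  names(networks) <- mo$network_label

  # --- BAN -----------------------------------------------------------------
  bone <- study$truth$bone_genes
  universe <- setNames(sum(lengths(lapply(networks[[1]], `[[`, "nodes"))),
                       mo$network_label)
  ban <- run_ban(networks, bone, universe_size_pre_prune = universe,
                 steps = config$ban$steps,
                 p_threshold = config$ban$p_threshold)

  # --- coloc ---------------------------------------------------------------
  co <- config$coloc
  proximity <- genes_near_leads(study$gene_table, leads,
                                max_dist = config$integrate$proximity_bp)
  bans_near <- ban$gene[ban$is_ban & proximity[ban$gene]]
  priors <- coloc_priors(co$p1, co$p2, co$p12, co$prior_effect_sd)
  coloc_tbl <- purrr::map_dfr(bans_near, function(g) {
    gi <- match(g, study$gene_table$gene_id)
    on_chrom <- leads[leads$chrom == study$gene_table$chrom[gi], ]
    mid <- (study$gene_table$start[gi] + study$gene_table$end[gi]) / 2
    lead <- on_chrom[which.min(abs(on_chrom$pos - mid)), ]
    scenario <- if (g %in% study$truth$driver_genes) "H4" else "H1"
    pair <- gen_assoc_pair(
      scenario, n_snps = co$n_snps, ld_rho = co$ld_rho,
      n1 = co$n1, n2 = co$n2, var_explained = co$var_explained,
      seed = derive_seed(seed, 6, match(g, study$gene_table$gene_id)),
      chrom = lead$chrom, start_bp = lead$pos - co$window,
      spacing_bp = max(1, floor(2 * co$window / max(co$n_snps - 1, 1)))
    )
    res <- run_coloc_scan(pair$gwas, pair$eqtl, lead$pos,
                          window = co$window, priors = priors,
                          pph4_threshold = co$pph4_threshold)
    dplyr::bind_cols(tibble::tibble(gene = g, lead_snp = lead$snp_id,
                                    scenario = scenario),
                     glance.coloc_result(res),
                     tibble::tibble(pph0 = res$pph0, pph1 = res$pph1,
                                    pph2 = res$pph2, pph3 = res$pph3))
  })
  if (!nrow(coloc_tbl)) {
    coloc_tbl <- tibble::tibble(gene = character(0), lead_snp = character(0),
                                scenario = character(0), n_snps = integer(0),
                                pph4 = numeric(0), colocalizing = logical(0),
                                pph0 = numeric(0), pph1 = numeric(0),
                                pph2 = numeric(0), pph3 = numeric(0))
  }

  # --- integrate -----------------------------------------------------------
  candidates <- candidate_report(ban, coloc_tbl, proximity)
  planted <- study$truth$driver_genes
  called <- candidates$gene[candidates$candidate]
  precision <- if (length(called)) mean(called %in% planted) else NA_real_
  recall <- mean(planted %in% called)

  hw <- config$integrate$locus_half_width
  loci <- tibble::tibble(
    chrom = leads$chrom, start = pmax(0, leads$pos - hw),
    end = leads$pos + hw,
    label = leads$snp_id
  ) |> head(10)
  overlap <- interval_overlap_null(loci, leads, study$truth$chrom_sizes,
                                   n_perm = config$integrate$n_perm,
                                   seed = derive_seed(seed, 7))
  bone_prox <- intersect(bone, ban$gene[ban$is_ban & proximity[ban$gene]])
  a <- sum(called %in% bone)
  b <- length(called) - a
  cc <- length(setdiff(bone_prox, called))
  d <- length(setdiff(bans_near, called)) - cc
  enrichment <- if ((a + b) > 0 && (cc + d) > 0) {
    fisher_enrichment(a, b, cc, max(d, 0))
  } else {
    tibble::tibble(odds_ratio = NA_real_, p = 1, estimable = FALSE)
  }

  params <- unclass(config)
  params$out_dir <- NULL
  report <- list(
    schema_version = 1L,
    seed = seed,
    parameters = params,
    counts = list(
      genes_simulated = nrow(study$counts$counts),
      genes_expressed = length(expressed),
      genes_in_network = length(net_genes),
      modules_detected = length(partition$module_sizes),
      genes_tested_ban = nrow(ban),
      bans = sum(ban$is_ban),
      bans_near_lead = length(bans_near),
      colocalizing = sum(coloc_tbl$colocalizing),
      candidates = length(called)
    ),
    module_recovery_ari = ari,
    candidate_precision = precision,
    candidate_recall = recall,
    overlap_observed = overlap$observed,
    overlap_percentile = overlap$percentile,
    enrichment_odds_ratio = enrichment$odds_ratio,
    enrichment_p = enrichment$p
  )

  out <- structure(list(
    report = report, study = study, leads = leads, partition = partition,
    networks = networks, ban = ban, coloc = coloc_tbl,
    candidates = candidates, proximity = proximity,
    overlap_null = overlap, enrichment = enrichment, expr = expr
  ), class = "netban_run")

  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_counts_tsv(run$study$counts, fp("counts.tsv"), fp("tpm.tsv"))
  readr::write_tsv(run$study$covariates, fp("covariates.tsv"))
  readr::write_tsv(run$study$gene_table, fp("gene_table.tsv"))
  readr::write_lines(run$study$truth$bone_genes, fp("bone_genes.txt"))
  readr::write_tsv(run$leads, fp("leads.tsv"))
  write_partition_tsv(run$partition, fp("partition.tsv"))
  write_networks_tsv(run$networks, fp("networks.tsv"))
  readr::write_tsv(run$ban, fp("ban.tsv"))
  readr::write_tsv(run$coloc, fp("coloc.tsv"))
  readr::write_tsv(run$candidates, fp("candidates.tsv"))
  jsonlite::write_json(run$report, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.netban_run <- function(x, ...) {
  ct <- x$report$counts
  cat(sprintf(paste0(
    "<netban_run> seed %d\n",
    "  genes: %d simulated, %d expressed, %d in network\n",
    "  modules: %d (ARI vs truth %.3f)\n",
    "  BAN: %d tested, %d called, %d near a lead\n",
    "  coloc: %d colocalizing; candidates: %d ",
    "(precision %.2f, recall %.2f)\n"),
    x$report$seed, ct$genes_simulated, ct$genes_expressed,
    ct$genes_in_network, ct$modules_detected, x$report$module_recovery_ari,
    ct$genes_tested_ban, ct$bans, ct$bans_near_lead, ct$colocalizing,
    ct$candidates, x$report$candidate_precision, x$report$candidate_recall))
  invisible(x)
}
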