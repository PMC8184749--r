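#' Simulation configuration for a synthetic expression study
#'
#' Bundles the knobs of the synthetic RNA-seq generator. The defaults define
#' the package's reference study: 200 samples, five planted co-expression
#' modules of 40 genes with factor loading 0.8, 100 unstructured background
#' genes, two sequencing batches and 30% known-bone-gene labels per module.
#'
#' @param n_samples Number of samples (columns).
#' @param n_modules Number of planted co-expression modules.
#' @param genes_per_module Genes per module (at least 2).
#' @param n_background_genes Genes with no module structure.
#' @param loading_range Interval in (0, 1) the per-gene factor loading is
#'   drawn from; a degenerate interval `c(x, x)` fixes the loading at `x`.
#' @param count_dispersion Negative-binomial dispersion shared by all genes
#'   (`size = 1/count_dispersion`); larger means noisier counts.
#' @param n_batches Number of batches samples are split into.
#' @param batch_shift_sd SD of the per-gene, per-batch shift on the log
#'   latent scale; 0 disables batch effects.
#' @param bone_gene_fraction Fraction of a bone module's genes that are
#'   labelled known bone genes.
#' @param bone_modules Indices of the modules that carry bone-gene labels;
#'   default the first half (rounded down, at least one) — in real
#'   co-expression studies only a minority of modules represent
#'   bone-cell processes. Their driver genes are the planted causal genes.
#' @param seed Integer seed; fixing it makes the generated study
#'   byte-identical across calls.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_modules = 5, genes_per_module = 40,
                       n_background_genes = 100,
                       loading_range = c(0.8, 0.8),
                       count_dispersion = 0.1, n_batches = 2,
                       batch_shift_sd = 0.3, bone_gene_fraction = 0.3,
                       bone_modules = NULL, seed = 1) {
  assert_count(n_samples, "n_samples")
  assert_count(n_modules, "n_modules")
  assert_count(genes_per_module, "genes_per_module")
  assert_count(n_background_genes, "n_background_genes", min = 0)
  assert_count(n_batches, "n_batches")
  if (genes_per_module < 2) abort("`genes_per_module` must be at least 2")
  if (length(loading_range) != 2 || any(loading_range <= 0) ||
      any(loading_range >= 1) || loading_range[1] > loading_range[2]) {
    abort("`loading_range` must be an interval within (0, 1)")
  }
  if (!is.numeric(count_dispersion) || count_dispersion <= 0) {
    abort("`count_dispersion` must be > 0")
  }
  if (batch_shift_sd < 0) abort("`batch_shift_sd` must be >= 0")
  assert_prob(bone_gene_fraction, "bone_gene_fraction")
  if (is.null(bone_modules)) {
    bone_modules <- seq_len(max(1, floor(n_modules / 2)))
  }
  if (any(bone_modules < 1 | bone_modules > n_modules)) {
    abort("`bone_modules` must index existing modules")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_modules = as.integer(n_modules),
    genes_per_module = as.integer(genes_per_module),
    n_background_genes = as.integer(n_background_genes),
    loading_range = as.numeric(loading_range),
    count_dispersion = count_dispersion, n_batches = as.integer(n_batches),
    batch_shift_sd = batch_shift_sd, bone_gene_fraction = bone_gene_fraction,
    bone_modules = as.integer(bone_modules),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Raw count container
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param tpm Optional numeric matrix of the same shape with TPM values.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, tpm = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("duplicate gene or sample ids in `counts`")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers")
  }
  if (!is.null(tpm) && !identical(dim(tpm), dim(counts))) {
    abort("`tpm` must have the same shape as `counts`")
  }
  structure(list(counts = counts, tpm = tpm,
                 gene_ids = rownames(counts), sample_ids = colnames(counts)),
            class = "count_matrix")
}

# Planted per-module DAG: a breadth-first tree rooted at the module's
# driver gene, with positive edge weights. The driver is a hub (branching
# `root_branching`); deeper nodes branch by `branching`, so distal leaves
# have small neighborhoods. Genes early in breadth-first order sit close
# to the driver; bone-gene labels are given to those positions so the
# driver's 3-step neighborhood is bone-enriched while leaves are not.
planted_module_dag <- function(genes, branching = 2, root_branching = 4) {
  g <- length(genes)
  edges <- tibble::tibble(from = character(), to = character(),
                          weight = numeric())
  depth <- integer(g)
  if (g > 1) {
    cap <- c(root_branching, rep(branching, g - 1))
    parent <- integer(g - 1)
    p <- 1L
    used <- 0L
    for (i in 2:g) {
      while (used >= cap[p]) { p <- p + 1L; used <- 0L }
      parent[i - 1] <- p
      used <- used + 1L
      depth[i] <- depth[p] + 1L
    }
    # moderate weights: enough signal for structure learning, while the
    # shared module factor still dominates pairwise correlation
    edges <- tibble::tibble(
      from = genes[parent],
      to = genes[2:g],
      weight = runif(g - 1, 0.4, 0.75)
    )
  }
  net <- directed_network(genes, edges)
  attr(net, "depth") <- setNames(depth, genes)
  net
}

# Bone-gene positions for a module: the deepest tree positions still within
# 3 steps of the driver (depth 3, then 2, then 1). Placing them at the
# driver's reach horizon makes the driver's neighborhood uniquely
# bone-enriched: other hubs reach only their own subtree's share.
bone_positions <- function(dagm, n_bone) {
  depth <- attr(dagm, "depth")
  eligible <- names(depth)[depth >= 1 & depth <= 3]
  eligible <- eligible[order(-depth[eligible], match(eligible, names(depth)))]
  eligible[seq_len(min(n_bone, length(eligible)))]
}

#' Generate a synthetic expression study with planted modules
#'
#' Simulates an RNA-seq count matrix over planted co-expression modules. Per
#' module m an eigengene vector `e_m` is drawn standard normal over samples;
#' gene g in m has log-scale latent signal `lambda * e_m +
#' sqrt(1 - lambda^2) * u_g` with loading `lambda` drawn from
#' `loading_range` and `u_g` the gene's column of a standardized
#' linear-Gaussian SEM sample from the module's planted DAG (so network
#' structure survives in the within-module residuals). Counts are negative
#' binomial with mean `exp(baseline + latent + batch shift)` and shared
#' dispersion. Background genes are independent noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `expr_study` with elements `counts`
#'   (a [count_matrix()] including TPM), `covariates` (tibble:
#'   `sample_id, sex, batch, age_days`), `gene_table` (tibble:
#'   `gene_id, chrom, start, end, length, human_homolog, is_known_bone`)
#'   and `truth` (module map, planted DAGs, bone/driver gene sets, and the
#'   noise-free latent matrix).
#' @export
gen_expression_study <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  with_seed(config$seed, {
    ns <- config$n_samples
    gm <- config$genes_per_module
    nm <- config$n_modules
    nb <- config$n_background_genes
    ng <- nm * gm + nb
    gene_ids <- sprintf("gene%04d", seq_len(ng))
    sample_ids <- sprintf("S%03d", seq_len(ns))
    module_names <- paste0("mod", seq_len(nm))

    module_of_gene <- rep("background", ng)
    names(module_of_gene) <- gene_ids

    latent <- matrix(0, ng, ns, dimnames = list(gene_ids, sample_ids))
    planted_dag <- list()
    bone_genes <- character()
    driver_genes <- character()

    for (m in seq_len(nm)) {
      idx <- ((m - 1) * gm + 1):(m * gm)
      genes <- gene_ids[idx]
      module_of_gene[idx] <- module_names[m]
      dagm <- planted_module_dag(genes)
      planted_dag[[module_names[m]]] <- dagm
      driver <- genes[1]
      if (m %in% config$bone_modules) {
        driver_genes <- c(driver_genes, driver)
        n_bone <- min(gm - 1, ceiling(config$bone_gene_fraction * gm))
        if (n_bone > 0) bone_genes <- c(bone_genes, bone_positions(dagm, n_bone))
      }
      e_m <- rnorm(ns)
      u <- gen_sem_data(dagm, weights = dagm$edges$weight, n = ns,
                        seed = derive_seed(config$seed, 101, m))
      u <- t(scale(t(u)))  # per-gene standardized SEM residual structure
      lambda <- runif(gm, config$loading_range[1], config$loading_range[2])
      latent[idx, ] <- lambda * matrix(e_m, gm, ns, byrow = TRUE) +
        sqrt(1 - lambda^2) * u
    }
    if (nb > 0) {
      idx <- (nm * gm + 1):ng
      latent[idx, ] <- matrix(rnorm(nb * ns), nb, ns)
    }

    # contiguous batch blocks; sex alternates within them, so sex and batch
    # stay estimable together
    batch <- paste0("B", rep(seq_len(config$n_batches),
                             each = ceiling(ns / config$n_batches),
                             length.out = ns))
    shift <- matrix(0, ng, ns)
    if (config$n_batches > 1 && config$batch_shift_sd > 0) {
      delta <- matrix(rnorm(ng * config$n_batches, 0, config$batch_shift_sd),
                      ng, config$n_batches)
      shift <- delta[, rep_len(seq_len(config$n_batches), ns), drop = FALSE]
    }

    baseline <- runif(ng, log(20), log(400))
    mu <- exp(baseline + latent + shift)
    counts <- matrix(
      rnbinom(ng * ns, mu = as.vector(mu), size = 1 / config$count_dispersion),
      ng, ns, dimnames = list(gene_ids, sample_ids)
    )

    gene_length <- sample(500:5000, ng, replace = TRUE)
    rate <- counts / gene_length
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
    dimnames(tpm) <- dimnames(counts)

    chrom_sizes <- c(`1` = 6e7, `2` = 6e7, `3` = 6e7)
    chrom <- sample(names(chrom_sizes), ng, replace = TRUE)
    start <- floor(runif(ng, 0, unname(chrom_sizes[chrom]) - gene_length))
    gene_table <- tibble::tibble(
      gene_id = gene_ids, chrom = chrom, start = start,
      end = start + gene_length, length = gene_length,
      human_homolog = toupper(gene_ids),
      is_known_bone = gene_ids %in% bone_genes
    )

    covariates <- tibble::tibble(
      sample_id = sample_ids,
      sex = rep_len(c("F", "M"), ns),
      batch = batch,
      age_days = sample(90:160, ns, replace = TRUE)
    )

    structure(list(
      counts = count_matrix(counts, tpm),
      covariates = covariates,
      gene_table = gene_table,
      truth = list(
        module_of_gene = module_of_gene,
        planted_dag = planted_dag,
        bone_genes = sort(bone_genes),
        driver_genes = driver_genes,
        latent = latent,
        chrom_sizes = chrom_sizes,
        coloc_scenario = NA_character_,
        causal_snp_indices = list()
      )
    ), class = "expr_study")
  })
}

#' Sample a linear-Gaussian SEM from a DAG
#'
#' Columns are generated in topological order: each node is the weighted sum
#' of its parents plus unit-variance Gaussian noise.
#'
#' @param dag A [directed_network()]; must be acyclic.
#' @param weights Numeric vector of edge weights aligned with `dag$edges`
#'   rows; defaults to the `weight` column of `dag$edges` if present.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric matrix, genes x samples, rownames = `dag$nodes`.
#' @export
gen_sem_data <- function(dag, weights = NULL, n, seed) {
  if (!inherits(dag, "bn_network")) abort("`dag` must be a bn_network")
  ord <- topological_order(dag)
  if (is.null(ord)) {
    abort("`dag` contains a directed cycle", class = "netban_cyclic_error")
  }
  if (is.null(weights)) weights <- dag$edges$weight
  if (is.null(weights) || length(weights) != nrow(dag$edges)) {
    abort("`weights` must supply one value per edge")
  }
  assert_count(n, "n")
  with_seed(seed, {
    p <- length(dag$nodes)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, dag$nodes))
    if (nrow(dag$edges)) {
      for (node in ord) {
        rows <- which(dag$edges$to == node)
        if (length(rows)) {
          pa <- dag$edges$from[rows]
          x[, node] <- x[, node] +
            x[, pa, drop = FALSE] %*% weights[rows]
        }
      }
    }
    t(x)
  })
}

#' Random DAG with bounded in-degree
#'
#' Utility for structure-recovery simulations: draws a DAG on `n_nodes`
#' nodes with each node receiving up to `max_in_degree` parents chosen
#' uniformly among its predecessors in a random topological order, and edge
#' weights uniform in `weight_range` with random sign.
#'
#' @param n_nodes Number of nodes.
#' @param max_in_degree Maximum parents per node.
#' @param weight_range Magnitude range for edge weights.
#' @param seed Integer seed.
#' @return A [directed_network()] whose `edges` carry a `weight` column.
#' @export
random_dag <- function(n_nodes, max_in_degree = 2, weight_range = c(0.5, 1.5),
                       seed = 1) {
  assert_count(n_nodes, "n_nodes")
  with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n_nodes))
    ord <- sample(nodes)
    from <- character(); to <- character()
    for (i in seq_along(ord)[-1]) {
      k <- sample(0:min(max_in_degree, i - 1), 1)
      if (k > 0) {
        pa <- sample(ord[seq_len(i - 1)], k)
        from <- c(from, pa)
        to <- c(to, rep(ord[i], k))
      }
    }
    w <- runif(length(from), weight_range[1], weight_range[2]) *
      sample(c(-1, 1), length(from), replace = TRUE)
    directed_network(nodes, tibble::tibble(from = from, to = to, weight = w))
  })
}

# --- paired GWAS/eQTL summary statistics -----------------------------------

# One cohort's haplotype-level allele matrix (n x p) as a heterogeneous
# binary Markov chain across SNPs, calibrated so adjacent allele (and hence
# dosage) correlation hits `rho` where the Frechet bounds allow.
sim_alleles <- function(n, maf, rho) {
  p <- length(maf)
  h <- matrix(0L, n, p)
  h[, 1] <- rbinom(n, 1, maf[1])
  if (p > 1) {
    for (j in 2:p) {
      pj <- maf[j - 1]; qj <- maf[j]
      p11 <- qj * pj + rho * sqrt(pj * (1 - pj) * qj * (1 - qj))
      p11 <- min(max(p11, max(0, pj + qj - 1)), min(pj, qj))
      cond1 <- p11 / pj
      cond0 <- (qj - p11) / (1 - pj)
      pr <- ifelse(h[, j - 1] == 1L, cond1, cond0)
      h[, j] <- rbinom(n, 1, pr)
    }
  }
  h
}

# Marginal (per-SNP) least-squares summary statistics of y on each dosage.
marginal_stats <- function(x, y) {
  n <- length(y)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, y - mean(y)))
  beta <- sxy / sxx
  syy <- sum((y - mean(y))^2)
  rss <- syy - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  list(beta = beta, se = se)
}

#' Generate paired GWAS and eQTL summary statistics
#'
#' Simulates two independent cohorts of genotype dosages over the same SNP
#' panel with AR(1)-style linkage disequilibrium, plants causal SNPs
#' according to one of the five colocalization hypotheses, and returns the
#' marginal regression summary statistics for each trait.
#'
#' MAFs are marginally Uniform(0.05, 0.5) but drawn through a Gaussian
#' copula with the same correlation parameter, so SNPs in strong LD have
#' similar frequencies and the target dosage correlation is attainable.
#'
#' @param scenario One of `"H0"` (no association), `"H1"` (trait 1 only),
#'   `"H2"` (trait 2 only), `"H3"` (both, two distinct SNPs), `"H4"` (both,
#'   one shared SNP).
#' @param n_snps Number of SNPs in the region.
#' @param ld_rho Target adjacent-SNP dosage correlation in `[0, 1)`.
#' @param n1,n2 Cohort sizes for trait 1 (GWAS) and trait 2 (eQTL).
#' @param var_explained Trait variance explained by each causal SNP, in
#'   (0, 1).
#' @param seed Integer seed.
#' @param chrom Chromosome label for the emitted positions.
#' @param start_bp,spacing_bp Base-pair position of the first SNP and
#'   spacing between consecutive SNPs.
#' @return A list with `gwas` and `eqtl` summary-statistic tibbles
#'   (`snp, chr, bp, beta, se, maf, n`) and `truth` (scenario and per-trait
#'   causal SNP indices).
#' @export
gen_assoc_pair <- function(scenario, n_snps = 100, ld_rho = 0.9,
                           n1 = 5000, n2 = 5000, var_explained = 0.01,
                           seed = 1, chrom = "1", start_bp = 1e6,
                           spacing_bp = 2000) {
  scenario <- match.arg(scenario, c("H0", "H1", "H2", "H3", "H4"))
  assert_count(n_snps, "n_snps", min = 1)
  assert_prob(ld_rho, "ld_rho", 0, 1, open = FALSE)
  if (ld_rho >= 1) abort("`ld_rho` must be < 1")
  assert_count(n1, "n1"); assert_count(n2, "n2")
  if (!is.numeric(var_explained) || var_explained <= 0 ||
      var_explained >= 1) {
    abort("`var_explained` must be in (0, 1)")
  }
  with_seed(seed, {
    # Smooth MAF process, marginally U(0.05, 0.5). The copula correlation
    # is pushed above ld_rho because the attainable correlation of two
    # binary alleles collapses as their frequencies separate; near-equal
    # neighboring MAFs keep the target dosage correlation feasible.
    maf_rho <- 1 - (1 - ld_rho) / 10
    z <- numeric(n_snps)
    z[1] <- rnorm(1)
    if (n_snps > 1) {
      for (j in 2:n_snps) {
        z[j] <- maf_rho * z[j - 1] + sqrt(1 - maf_rho^2) * rnorm(1)
      }
    }
    maf <- 0.05 + 0.45 * pnorm(z)

    pick_causal <- function(frac) {
      target <- max(1, round(frac * n_snps))
      eligible <- which(maf >= 0.15)
      if (!length(eligible)) eligible <- which.max(maf)
      eligible[which.min(abs(eligible - target))]
    }
    causal1 <- integer(0); causal2 <- integer(0)
    if (scenario %in% c("H1", "H3")) causal1 <- pick_causal(0.25)
    if (scenario %in% c("H2", "H3")) causal2 <- pick_causal(0.75)
    if (scenario == "H4") causal1 <- causal2 <- pick_causal(0.5)

    sim_cohort <- function(n, causal) {
      x <- sim_alleles(n, maf, ld_rho) + sim_alleles(n, maf, ld_rho)
      y <- rnorm(n)
      if (length(causal)) {
        ve_tot <- length(causal) * var_explained
        y <- y * sqrt(1 - ve_tot)
        for (cs in causal) {
          b <- sqrt(var_explained / (2 * maf[cs] * (1 - maf[cs])))
          y <- y + b * (x[, cs] - 2 * maf[cs])
        }
      }
      st <- marginal_stats(x, y)
      freq <- colMeans(x) / 2
      tibble::tibble(
        snp = sprintf("rs%04d", seq_len(n_snps)),
        chr = chrom,
        bp = start_bp + (seq_len(n_snps) - 1) * spacing_bp,
        beta = st$beta, se = st$se,
        maf = pmin(freq, 1 - freq), n = n
      )
    }
    gwas <- sim_cohort(n1, causal1)
    eqtl <- sim_cohort(n2, causal2)
    list(
      gwas = gwas, eqtl = eqtl,
      truth = list(
        coloc_scenario = scenario,
        causal_snp_indices = list(trait1 = causal1, trait2 = causal2),
        maf = maf
      )
    )
  })
}

#' Generate a random gene landscape and lead-SNP catalog
#'
#' Places gene intervals and GWAS lead-SNP positions uniformly at random on
#' the supplied chromosomes.
#'
#' @param n_genes,n_leads Numbers of genes and lead SNPs to place.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param seed Integer seed.
#' @param gene_length_range Interval gene lengths are drawn from.
#' @return A list with `genes` (tibble `gene_id, chrom, start, end`,
#'   0-based half-open) and `leads` (tibble `snp_id, chrom, pos`).
#' @export
gen_gene_landscape <- function(n_genes, n_leads, chrom_sizes, seed = 1,
                               gene_length_range = c(5e3, 2e5)) {
  assert_count(n_genes, "n_genes", min = 0)
  assert_count(n_leads, "n_leads", min = 0)
  if (!length(chrom_sizes) || is.null(names(chrom_sizes))) {
    abort("`chrom_sizes` must be a nonempty named vector")
  }
  if (gene_length_range[2] > max(chrom_sizes)) {
    abort("gene length range exceeds every chromosome size")
  }
  with_seed(seed, {
    lens <- if (n_genes) {
      floor(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    } else numeric(0)
    place <- function(len) {
      fits <- chrom_sizes[chrom_sizes >= len]
      ch <- sample(names(fits), 1, prob = fits)
      c(ch, floor(runif(1, 0, chrom_sizes[[ch]] - len)))
    }
    genes <- tibble::tibble(gene_id = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0))
    if (n_genes) {
      placed <- vapply(lens, place, character(2))
      genes <- tibble::tibble(
        gene_id = sprintf("gene%04d", seq_len(n_genes)),
        chrom = placed[1, ],
        start = as.numeric(placed[2, ]),
        end = as.numeric(placed[2, ]) + lens
      )
    }
    leads <- tibble::tibble(snp_id = character(0), chrom = character(0),
                            pos = numeric(0))
    if (n_leads) {
      ch <- sample(names(chrom_sizes), n_leads, replace = TRUE,
                   prob = chrom_sizes)
      leads <- tibble::tibble(
        snp_id = sprintf("lead%03d", seq_len(n_leads)),
        chrom = ch,
        pos = floor(runif(n_leads, 0, unname(chrom_sizes[ch])))
      )
    }
    list(genes = genes, leads = leads)
  })
}
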