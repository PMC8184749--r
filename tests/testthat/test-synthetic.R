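test_that("expression study plants the configured module structure and is deterministic", {
  cfg <- sim_config(n_samples = 50, n_modules = 5, genes_per_module = 40,
                    n_background_genes = 30, seed = 3)
  st <- gen_expression_study(cfg)
  blocks <- table(st$truth$module_of_gene)
  mods <- blocks[names(blocks) != "background"]
  expect_length(mods, 5)
  expect_true(all(mods == 40))
  expect_equal(unname(blocks["background"]), 30)
  expect_equal(dim(st$counts$counts), c(230, 50))
  expect_true(all(st$counts$counts >= 0))
  expect_true(all(st$counts$counts == round(st$counts$counts)))

  st2 <- gen_expression_study(cfg)
  expect_identical(st$counts$counts, st2$counts$counts)
  expect_identical(st$truth$bone_genes, st2$truth$bone_genes)

  st3 <- gen_expression_study(sim_config(n_samples = 50, n_modules = 5,
                                         genes_per_module = 40,
                                         n_background_genes = 30, seed = 4))
  expect_false(identical(st$counts$counts, st3$counts$counts))

  expect_error(sim_config(genes_per_module = 1), "genes_per_module")
})

test_that("within-module latent correlation matches the shared-factor value lambda^2", {
  st <- gen_expression_study(sim_config(
    n_samples = 500, n_modules = 3, genes_per_module = 30,
    n_background_genes = 10, loading_range = c(0.8, 0.8), seed = 7))
  cors <- c()
  for (m in paste0("mod", 1:3)) {
    genes <- names(st$truth$module_of_gene)[st$truth$module_of_gene == m]
    cm <- cor(t(st$truth$latent[genes, ]))
    cors <- c(cors, cm[upper.tri(cm)])
  }
  expect_lt(abs(mean(cors) - 0.64), 0.05)
})

test_that("SEM sampler honors the DAG, matches the closed-form covariance, rejects cycles", {
  chain <- directed_network(c("X", "Y", "Z"),
                            data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  m <- gen_sem_data(chain, weights = c(1, 1), n = 50000, seed = 5)
  expect_identical(m, gen_sem_data(chain, weights = c(1, 1), n = 50000,
                                   seed = 5))
  S <- cov(t(m))
  B <- matrix(0, 3, 3, dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  B["X", "Y"] <- 1; B["Y", "Z"] <- 1
  S_theory <- solve(t(diag(3) - B)) %*% solve(diag(3) - B)
  expect_lt(max(abs(S - S_theory)), 0.12)
  expect_lt(abs(S["X", "Z"] - 1), 0.1)

  m0 <- gen_sem_data(chain, weights = c(0, 0), n = 20000, seed = 6)
  c0 <- cor(t(m0))
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.05)

  expect_error(
    directed_network(c("a", "b"), data.frame(from = c("a", "b"),
                                             to = c("b", "a"))),
    class = "netban_cyclic_error"
  )
})

test_that("association pairs encode the five hypotheses with the stated marginal power", {
  h0 <- gen_assoc_pair("H0", seed = 1)
  expect_length(h0$truth$causal_snp_indices$trait1, 0)
  expect_length(h0$truth$causal_snp_indices$trait2, 0)

  h4 <- gen_assoc_pair("H4", seed = 1)
  expect_identical(h4$truth$causal_snp_indices$trait1,
                   h4$truth$causal_snp_indices$trait2)
  expect_length(h4$truth$causal_snp_indices$trait1, 1)

  h3 <- gen_assoc_pair("H3", seed = 1)
  expect_false(h3$truth$causal_snp_indices$trait1 ==
                 h3$truth$causal_snp_indices$trait2)

  # mean |z| at the causal SNP ~ sqrt(n * ve / (1 - ve)) ~ 7.1
  zs <- vapply(1:50, function(s) {
    ap <- gen_assoc_pair("H1", n_snps = 30, seed = s, n1 = 5000, n2 = 200)
    i <- ap$truth$causal_snp_indices$trait1
    abs(ap$gwas$beta[i] / ap$gwas$se[i])
  }, numeric(1))
  expect_lt(abs(mean(zs) - sqrt(5000 * 0.01 / 0.99)), 1)

  expect_error(gen_assoc_pair("H4", var_explained = 1), "var_explained")
})

test_that("simulated dosages match the target MAF range and LD decay", {
  ap <- gen_assoc_pair("H0", n_snps = 60, ld_rho = 0.9, n1 = 8000, n2 = 200,
                       seed = 9)
  expect_true(all(ap$gwas$maf >= 0.03 & ap$gwas$maf <= 0.5))
  # re-simulate dosages through the internal allele model to measure LD
  maf <- ap$truth$maf
  set.seed(42)
  x <- netban:::sim_alleles(8000, maf, 0.9) + netban:::sim_alleles(8000, maf, 0.9)
  cc <- vapply(seq_len(59), function(j) cor(x[, j], x[, j + 1]), numeric(1))
  expect_lt(abs(mean(cc) - 0.9), 0.05)
})

test_that("gene landscape respects chromosome bounds and determinism", {
  sizes <- c(chr1 = 5e7, chr2 = 3e7)
  gl <- gen_gene_landscape(100, 12, sizes, seed = 2)
  expect_equal(nrow(gl$genes), 100)
  expect_equal(nrow(gl$leads), 12)
  expect_true(all(gl$genes$start >= 0))
  expect_true(all(gl$genes$end <= sizes[gl$genes$chrom]))
  expect_true(all(gl$leads$pos < sizes[gl$leads$chrom]))

  expect_identical(gl, gen_gene_landscape(100, 12, sizes, seed = 2))
  expect_equal(nrow(gen_gene_landscape(5, 0, sizes, seed = 1)$leads), 0)
  expect_error(gen_gene_landscape(5, 1, c(chr1 = 1e4), seed = 1,
                                  gene_length_range = c(5e4, 6e4)),
               "chromosome")
})

test_that("planted drivers sit within 3 steps of the module's bone genes", {
  st <- small_study(seed = 21)
  for (i in seq_along(st$truth$driver_genes)) {
    drv <- st$truth$driver_genes[i]
    mod <- st$truth$module_of_gene[drv]
    dag <- st$truth$planted_dag[[mod]]
    g <- igraph::graph_from_data_frame(dag$edges[c("from", "to")],
                                       directed = FALSE,
                                       vertices = dag$nodes)
    reach <- igraph::ego(g, order = 3, nodes = drv)[[1]]$name
    n_bone <- sum(reach %in% st$truth$bone_genes)
    expect_gte(n_bone, 10)
  }
})
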