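test_that("signed adjacency matches its closed forms and rejects constant genes", {
  u <- orthonormal_centered(20, 2, seed = 4)
  expr <- rbind(g1 = u[, 1], g2 = u[, 1], g3 = -u[, 1], g4 = u[, 2])
  colnames(expr) <- sprintf("s%02d", 1:20)
  adj <- signed_adjacency(expr, power = 4)
  expect_equal(adj$a["g1", "g2"], 1)            # cor  1 -> 1
  expect_equal(adj$a["g1", "g3"], 0)            # cor -1 -> 0
  expect_equal(adj$a["g1", "g4"], 0.5^4)        # cor  0 -> 0.0625
  expect_true(all(diag(adj$a) == 0))
  expect_true(isSymmetric(adj$a))

  bad <- rbind(expr, g5 = rep(1, 20))
  expect_error(signed_adjacency(bad), "g5")
})

test_that("topological overlap matches hand-computed values and its bounds", {
  # a12 = a13 = 0.5, a23 = 0 -> TOM_12 = 0.5
  a <- matrix(c(0, .5, .5, .5, 0, 0, .5, 0, 0), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  adj <- structure(list(a = a, power = 4, gene_ids = rownames(a)),
                   class = "adjacency")
  tm <- tom_similarity(adj)
  expect_equal(tm$tom["g1", "g2"], 0.5, tolerance = 1e-12)
  expect_true(all(diag(tm$tom) == 1))

  # complete graph with all a = 1 -> TOM 1 everywhere
  a1 <- matrix(1, 3, 3, dimnames = dimnames(a)); diag(a1) <- 0
  adj1 <- structure(list(a = a1, power = 4, gene_ids = rownames(a)),
                    class = "adjacency")
  expect_true(all(tom_similarity(adj1)$tom == 1))

  # two genes with a_ij = 0 and no shared neighbors -> TOM 0
  a0 <- matrix(0, 3, 3, dimnames = dimnames(a)); a0[1, 3] <- a0[3, 1] <- 0.7
  adj0 <- structure(list(a = a0, power = 4, gene_ids = rownames(a)),
                    class = "adjacency")
  expect_equal(tom_similarity(adj0)$tom["g1", "g2"], 0)

  # random case: bounds and the componentwise lower bound
  set.seed(8)
  expr <- matrix(rnorm(30 * 50), 30, 50,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  adjr <- signed_adjacency(expr)
  tr <- tom_similarity(adjr)$tom
  expect_true(all(tr >= -1e-12 & tr <= 1 + 1e-12))
  k <- colSums(adjr$a)
  lower <- adjr$a / (outer(k, k, pmin) + 1 - adjr$a)
  off <- upper.tri(tr)
  expect_true(all(tr[off] >= lower[off] - 1e-12))
})

test_that("module eigengene equals the first right singular vector and aligns sign", {
  set.seed(12)
  n <- 40
  v <- rnorm(n)
  expr <- matrix(rep(v, each = 5), 5, n, byrow = FALSE)
  expr <- rbind(expr * runif(5, 0.5, 2))
  rownames(expr) <- sprintf("g%d", 1:5); colnames(expr) <- sprintf("s%d", 1:n)
  me <- module_eigengenes(expr, setNames(rep("M1", 5), rownames(expr)))
  sv <- scale(v)[, 1]
  expect_equal(abs(cor(me[, 1], sv)), 1, tolerance = 1e-12)
  expect_gt(cor(me[, 1], sv), 0)   # positively aligned with the mean profile
  expect_equal(sum(me[, 1]^2), 1)  # unit norm

  # two anti-correlated genes: tie broken toward the first gene by id
  expr2 <- rbind(gA = v, gB = -v)
  colnames(expr2) <- sprintf("s%d", 1:n)
  me2 <- module_eigengenes(expr2, setNames(rep("M1", 2), c("gA", "gB")))
  expect_gt(cor(me2[, 1], scale(v)[, 1]), 0.999)

  # SVD oracle on a random 30-gene module
  expr3 <- matrix(rnorm(30 * 50), 30, 50,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("s%02d", 1:50)))
  me3 <- module_eigengenes(expr3, setNames(rep("M1", 30), rownames(expr3)))
  sv3 <- svd(scale(t(expr3)))$u[, 1]
  if (sum(sv3 * rowMeans(scale(t(expr3)))) < 0) sv3 <- -sv3
  expect_equal(unname(me3[, 1]), sv3, tolerance = 1e-8)

  # single-gene module: the standardized gene itself
  me4 <- module_eigengenes(expr3, setNames("M1", "g01"))
  expect_equal(abs(cor(me4[, 1], expr3["g01", ])), 1, tolerance = 1e-12)
})

test_that("module detection handles degenerate inputs and ignores gene order", {
  # all genes carrying the same signal -> one module
  set.seed(5)
  v <- rnorm(50)
  expr <- matrix(rep(v, 40), 40, 50, byrow = TRUE) +
    matrix(rnorm(2000, 0, 1e-6), 40, 50)
  rownames(expr) <- sprintf("g%02d", 1:40); colnames(expr) <- paste0("s", 1:50)
  part <- detect_modules(tom_similarity(signed_adjacency(expr)), expr,
                         min_module_size = 30)
  expect_equal(length(part$module_sizes), 1)
  expect_true(all(part$module_of_gene == "M1"))

  # fewer genes than the minimum size -> everything unassigned, with warning
  expr_small <- expr[1:20, ]
  expect_warning(
    part_small <- detect_modules(tom_similarity(signed_adjacency(expr_small)),
                                 expr_small, min_module_size = 30),
    "unassigned")
  expect_true(all(part_small$module_of_gene == "unassigned"))

  # permuting genes gives the same partition up to labels
  st <- small_study(seed = 31, n_samples = 120, n_modules = 3,
                    genes_per_module = 35, n_background_genes = 40)
  expr2 <- normalize_adjust(st$counts, st$covariates, "batch", "sex")
  p1 <- detect_modules(tom_similarity(signed_adjacency(expr2)), expr2)
  perm <- sample(rownames(expr2))
  expr2p <- expr2[perm, ]
  p2 <- detect_modules(tom_similarity(signed_adjacency(expr2p)), expr2p)
  common <- rownames(expr2)
  expect_equal(
    mclust::adjustedRandIndex(p1$module_of_gene[common],
                              p2$module_of_gene[common]), 1)
})

test_that("eigengene-trait association is rank-based with calibrated nulls", {
  set.seed(77)
  me <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "M1"))
  tr <- cbind(same = me[, 1], mono = exp(me[, 1]))
  res <- eigengene_trait_assoc(me, tr)
  expect_equal(res$rho, c(1, 1))
  expect_true(all(res$p < 1e-10))

  # too few complete pairs -> flagged not estimable
  tr_na <- cbind(sparse = c(1, 2, 3, rep(NA, 57)))
  res_na <- eigengene_trait_assoc(me, tr_na)
  expect_false(res_na$estimable)
  expect_true(is.na(res_na$rho))

  # null calibration
  ps <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    eigengene_trait_assoc(me, cbind(t = rnorm(60)))$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})
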