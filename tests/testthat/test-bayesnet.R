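test_that("Fisher-z test matches its closed form and detects d-separation", {
  u <- orthonormal_centered(100, 2, seed = 9)
  x <- u[, 1]
  y <- 0.5 * u[, 1] + sqrt(0.75) * u[, 2]   # exact sample correlation 0.5
  dat <- rbind(X = x, Y = y)
  colnames(dat) <- sprintf("s%03d", 1:100)
  ft <- fisher_z_pcor_test(dat, "X", "Y")
  expect_equal(ft$r, 0.5, tolerance = 1e-6)
  expect_equal(ft$statistic, atanh(0.5) * sqrt(97), tolerance = 1e-6)
  expect_equal(ft$statistic, 5.4100, tolerance = 1e-4)
  expect_equal(ft$p, 6.3e-8, tolerance = 0.02)

  # exactly uncorrelated -> statistic 0, p 1
  dat0 <- rbind(X = u[, 1], Y = u[, 2])
  colnames(dat0) <- colnames(dat)
  ft0 <- fisher_z_pcor_test(dat0, "X", "Y")
  expect_equal(ft0$statistic, 0, tolerance = 1e-10)
  expect_equal(ft0$p, 1, tolerance = 1e-10)

  # duplicated gene -> degenerate
  datd <- rbind(X = x, Y = x)
  colnames(datd) <- colnames(dat)
  ftd <- fisher_z_pcor_test(datd, "X", "Y")
  expect_true(ftd$degenerate)
  expect_equal(ftd$p, 0)

  # chain X -> Y -> Z: X _||_ Z | Y
  chain <- directed_network(c("X", "Y", "Z"),
                            data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  m <- gen_sem_data(chain, weights = c(1, 1), n = 50000, seed = 13)
  expect_gt(fisher_z_pcor_test(m, "X", "Z", "Y")$p, 0.05)
  expect_lt(fisher_z_pcor_test(m, "X", "Z")$p, 1e-10)
})

test_that("MMPC recovers chain and collider skeletons and drops independent genes", {
  set.seed(2)
  ind <- matrix(rnorm(4 * 2000), 4, 2000,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(nrow(mmpc_skeleton(ind)$edges), 0)

  chain <- directed_network(c("X", "Y", "Z"),
                            data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  mc <- gen_sem_data(chain, weights = c(1, 1), n = 5000, seed = 3)
  sk <- mmpc_skeleton(mc)
  expect_equal(skeleton_shd(sk$edges, chain$edges), 0)

  collider <- directed_network(c("X", "Y", "Z"),
                               data.frame(from = c("X", "Y"),
                                          to = c("Z", "Z")))
  mk <- gen_sem_data(collider, weights = c(1, 1), n = 5000, seed = 4)
  skc <- mmpc_skeleton(mk)
  expect_equal(skeleton_shd(skc$edges, collider$edges), 0)
})

test_that("Gaussian BIC matches its closed form and an lm-based oracle", {
  # single node, n = 100, MLE residual variance exactly 1
  u <- orthonormal_centered(100, 1, seed = 5)
  x <- u[, 1] * 10                      # centered, sum of squares = 100
  dat <- rbind(X = x)
  colnames(dat) <- sprintf("s%03d", 1:100)
  single <- directed_network("X")
  expect_equal(gaussian_bic(dat, single),
               -(100 / 2) * (log(2 * pi) + 1) - log(100), tolerance = 1e-10)
  expect_equal(gaussian_bic(dat, single), -146.4991, tolerance = 1e-4)

  # decomposability + lm oracle on a random DAG
  dag <- random_dag(6, max_in_degree = 2, seed = 6)
  m <- gen_sem_data(dag, n = 300, seed = 7)
  total <- gaussian_bic(m, dag)
  n <- 300
  oracle <- sum(vapply(dag$nodes, function(v) {
    pa <- dag$edges$from[dag$edges$to == v]
    df <- data.frame(y = m[v, ])
    for (p in pa) df[[p]] <- m[p, ]
    fit <- lm(y ~ ., data = df)
    s2 <- sum(residuals(fit)^2) / n
    -n / 2 * (log(2 * pi) + log(s2) + 1) - (length(pa) + 2) / 2 * log(n)
  }, numeric(1)))
  expect_equal(total, oracle, tolerance = 1e-8)

  # a truly null parent lowers the score at large n
  worse <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    m2 <- matrix(rnorm(2 * 10000), 2, 10000,
                 dimnames = list(c("A", "B"), NULL))
    s_empty <- gaussian_bic(m2, directed_network(c("A", "B")))
    s_edge <- gaussian_bic(m2, directed_network(
      c("A", "B"), data.frame(from = "A", to = "B")))
    if (s_edge < s_empty) worse <- worse + 1
  }
  expect_equal(worse, 20)
})

test_that("hill climbing is greedy, acyclic, deterministic, and finds the skeleton-constrained optimum", {
  # empty skeleton -> empty DAG with the sum of marginal scores
  set.seed(8)
  m <- matrix(rnorm(3 * 500), 3, 500, dimnames = list(c("A", "B", "C"), NULL))
  empty_sk <- structure(list(nodes = c("A", "B", "C"),
                             edges = tibble::tibble(from = character(0),
                                                    to = character(0)),
                             sepsets = list()), class = "bn_skeleton")
  net0 <- hill_climb(m, empty_sk)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(net0$score, gaussian_bic(m, directed_network(c("A", "B", "C"))))

  # two strongly correlated genes -> exactly one edge, direction by tie-break
  u <- orthonormal_centered(400, 2, seed = 10)
  dat2 <- rbind(gA = u[, 1], gB = 0.9 * u[, 1] + sqrt(1 - 0.81) * u[, 2])
  colnames(dat2) <- sprintf("s%03d", 1:400)
  sk2 <- mmpc_skeleton(dat2)
  net2 <- hill_climb(dat2, sk2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$from, "gA")  # lexicographically first source wins
  expect_equal(net2$edges$to, "gB")

  # 4-node chain: greedy score equals the exhaustive skeleton-constrained max
  chain4 <- directed_network(c("W", "X", "Y", "Z"),
                             data.frame(from = c("W", "X", "Y"),
                                        to = c("X", "Y", "Z")))
  m4 <- gen_sem_data(chain4, weights = c(1, 1, 1), n = 2000, seed = 11)
  sk4 <- mmpc_skeleton(m4)
  net4 <- hill_climb(m4, sk4)
  dags <- all_skeleton_dags(sk4$nodes, sk4$edges)
  best <- max(vapply(dags, function(d) gaussian_bic(m4, d), numeric(1)))
  expect_equal(net4$score, best, tolerance = 1e-8)
  expect_false(is.null(topological_order(net4)))
})

test_that("learning is stable under gene-order permutation up to score-equivalent orientations", {
  st <- small_study(seed = 41, n_samples = 150, n_modules = 1,
                    genes_per_module = 15, n_background_genes = 0)
  expr <- normalize_adjust(st$counts, st$covariates, "batch", "sex")
  sk_a <- mmpc_skeleton(expr)
  perm <- rev(rownames(expr))
  sk_b <- mmpc_skeleton(expr[perm, ])
  expect_equal(skeleton_shd(sk_a$edges, sk_b$edges), 0)
  net_a <- hill_climb(expr, sk_a)
  net_b <- hill_climb(expr[perm, ], sk_b)
  expect_equal(net_a$score, net_b$score, tolerance = 1e-6)
  expect_equal(skeleton_shd(net_a$edges, net_b$edges), 0)
})
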