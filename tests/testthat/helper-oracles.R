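# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct combinatorial sums, exhaustive
# enumeration, and duplicate implementations.

# Upper-tail hypergeometric by direct combinatorial summation.
hyper_upper_oracle <- function(overlap, m, n_bg, k) {
  xs <- overlap:min(k, m)
  xs <- xs[k - xs <= n_bg & xs >= max(0, k - n_bg)]
  if (!length(xs)) return(0)
  sum(choose(m, xs) * choose(n_bg, k - xs)) / choose(m + n_bg, k)
}

# Five-hypothesis posteriors by enumeration over single-causal-SNP
# configurations per trait (H0: none; H1/H2: one trait causal at SNP i;
# H3: distinct SNPs; H4: shared SNP).
coloc_enum_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                              p12 = 1e-5) {
  bf1 <- exp(labf1)
  bf2 <- exp(labf2)
  n <- length(bf1)
  w0 <- 1
  w1 <- sum(p1 * bf1)
  w2 <- sum(p2 * bf2)
  w3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
    }
  }
  w4 <- sum(p12 * bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

# Two-sided Fisher exact p by enumerating all 2x2 tables with the observed
# margins and summing hypergeometric probabilities <= the observed one.
fisher_exact_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All DAGs whose edges are a subset of the given undirected skeleton
# pairs: each pair is absent, forward, or reverse; cyclic states dropped.
all_skeleton_dags <- function(nodes, pairs) {
  n_e <- nrow(pairs)
  out <- list()
  states <- expand.grid(rep(list(0:2), n_e))
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    from <- character(0); to <- character(0)
    for (k in seq_len(n_e)) {
      if (st[k] == 1) { from <- c(from, pairs$from[k]); to <- c(to, pairs$to[k]) }
      if (st[k] == 2) { from <- c(from, pairs$to[k]); to <- c(to, pairs$from[k]) }
    }
    net <- tryCatch(
      directed_network(nodes, tibble::tibble(from = from, to = to)),
      error = function(e) NULL
    )
    if (!is.null(net)) out[[length(out) + 1]] <- net
  }
  out
}

# Structural Hamming distance between two undirected edge sets given as
# data frames with from/to columns.
skeleton_shd <- function(edges_a, edges_b) {
  key <- function(e) {
    if (!nrow(e)) return(character(0))
    apply(cbind(pmin(e$from, e$to), pmax(e$from, e$to)), 1, paste,
          collapse = "|")
  }
  ka <- key(edges_a); kb <- key(edges_b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

# Orthonormal mean-zero columns for constructing data with exact sample
# correlations.
orthonormal_centered <- function(n, k, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  m <- scale(m, center = TRUE, scale = FALSE)
  qr.Q(qr(m))
}

# Small study used by several tests (kept cheap).
small_study <- function(seed = 11, ...) {
  gen_expression_study(sim_config(seed = seed, ...))
}
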