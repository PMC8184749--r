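#' Configuration for Bayesian-network structure learning
#'
#' @param alpha Level of the Fisher-z conditional-independence tests.
#' @param max_sepset Largest conditioning-set size searched.
#' @param max_iterations Hill-climbing iteration cap.
#' @param ridge Ridge added to correlation/covariance submatrices before
#'   inversion, for near-collinear genes.
#' @param max_genes Refuse modules larger than this (structure learning is
#'   super-quadratic in genes).
#' @return A list of class `bn_config`.
#' @export
bn_config <- function(alpha = 0.05, max_sepset = 3, max_iterations = 500,
                      ridge = 1e-8, max_genes = 1000) {
  assert_prob(alpha, "alpha", 0, 1, open = TRUE)
  assert_count(max_sepset, "max_sepset", min = 0)
  assert_count(max_iterations, "max_iterations")
  if (ridge < 0) abort("`ridge` must be >= 0")
  structure(list(alpha = alpha, max_sepset = as.integer(max_sepset),
                 max_iterations = as.integer(max_iterations), ridge = ridge,
                 max_genes = as.integer(max_genes)), class = "bn_config")
}

# partial correlation of i, j given S from a correlation (or covariance)
# matrix, via inversion of the ridge-stabilized submatrix
pcor_from_mat <- function(C, i, j, S, ridge = 1e-8) {
  sub <- C[c(i, j, S), c(i, j, S), drop = FALSE]
  om <- tryCatch(solve(sub + diag(ridge, nrow(sub))),
                 error = function(e) solve(sub + diag(1e-4, nrow(sub))))
  -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
}

#' Fisher-z test of (partial) correlation
#'
#' Tests whether genes `i` and `j` are conditionally independent given gene
#' set `S`: partial correlation `r` is computed by inverting the
#' ridge-stabilized correlation submatrix over `{i, j} U S`, then
#' `z = atanh(r) * sqrt(n - |S| - 3)` is referred to a standard normal.
#'
#' @param data Numeric matrix, genes x samples.
#' @param i,j Gene ids to test.
#' @param S Character vector of conditioning genes (possibly empty).
#' @param config A [bn_config()] (for `ridge`).
#' @return List with `r`, `statistic`, `p`, `df_n` and `degenerate`
#'   (`TRUE` when `|r| = 1`, in which case `p` is reported as 0).
#' @export
fisher_z_pcor_test <- function(data, i, j, S = character(),
                               config = bn_config()) {
  n <- ncol(data)
  if (n <= length(S) + 3) abort("need n > |S| + 3 samples")
  C <- cor(t(data[c(i, j, S), , drop = FALSE]))
  r <- pcor_from_mat(C, 1, 2, seq_along(S) + 2, config$ridge)
  if (abs(r) >= 1 - 1e-7) {
    return(list(r = r, statistic = sign(r) * Inf, p = 0,
                df_n = n - length(S) - 3, degenerate = TRUE))
  }
  z <- atanh(r) * sqrt(n - length(S) - 3)
  list(r = r, statistic = z, p = 2 * pnorm(-abs(z)),
       df_n = n - length(S) - 3, degenerate = FALSE)
}

# p-value helper used in the skeleton search (precomputed correlation)
pcor_pvalue <- function(C, n, i, j, S, ridge) {
  r <- pcor_from_mat(C, i, j, S, ridge)
  if (abs(r) >= 1 - 1e-12) return(0)
  2 * pnorm(-abs(atanh(r)) * sqrt(n - length(S) - 3))
}

subsets_up_to <- function(x, kmax) {
  out <- list(character(0))
  for (k in seq_len(min(kmax, length(x)))) {
    out <- c(out, combn(x, k, simplify = FALSE))
  }
  out
}

#' MMPC candidate skeleton
#'
#' Constraint-based phase of Max-Min Hill Climbing: per target, the
#' candidate parent/children set is grown by the max-min heuristic (add the
#' variable whose weakest association over subsets of the current set is
#' strongest) and shrunk by removing any member independent of the target
#' given some subset of the remaining members. The final skeleton keeps the
#' pair (i, j) only if each is in the other's set (AND symmetrization).
#'
#' @param data Numeric matrix, genes x samples (>= 2 genes).
#' @param config A [bn_config()].
#' @return List of class `bn_skeleton`: `nodes`, `edges` (tibble
#'   `from < to`), `sepsets` (list keyed `"i|j"`).
#' @export
mmpc_skeleton <- function(data, config = bn_config()) {
  genes <- rownames(data)
  p <- length(genes)
  if (p < 2) abort("need at least 2 genes")
  if (p > config$max_genes) {
    abort(sprintf("module of %d genes exceeds max_genes = %d", p,
                  config$max_genes))
  }
  n <- ncol(data)
  C <- cor(t(data))
  alpha <- config$alpha
  sepsets <- list()
  sep_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

  pc <- setNames(vector("list", p), genes)
  for (t in genes) {
    cpc <- character(0)
    candidates <- setdiff(genes, t)
    # forward (max-min) phase
    repeat {
      if (!length(candidates)) break
      best_x <- NA_character_
      best_p <- Inf
      drop <- character(0)
      for (x in candidates) {
        maxp <- 0
        sep <- NULL
        for (S in subsets_up_to(cpc, config$max_sepset)) {
          pv <- pcor_pvalue(C, n, x, t, S, config$ridge)
          if (pv > maxp) maxp <- pv
          if (pv > alpha) { sep <- S; break }
        }
        if (!is.null(sep)) {
          sepsets[[sep_key(x, t)]] <- sep
          drop <- c(drop, x)
        } else if (maxp < best_p) {
          best_p <- maxp
          best_x <- x
        }
      }
      candidates <- setdiff(candidates, drop)
      if (is.na(best_x)) break
      cpc <- c(cpc, best_x)
      candidates <- setdiff(candidates, best_x)
    }
    # backward (shrink) phase
    changed <- TRUE
    while (changed && length(cpc)) {
      changed <- FALSE
      for (x in cpc) {
        for (S in subsets_up_to(setdiff(cpc, x), config$max_sepset)) {
          if (pcor_pvalue(C, n, x, t, S, config$ridge) > alpha) {
            sepsets[[sep_key(x, t)]] <- S
            cpc <- setdiff(cpc, x)
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    pc[[t]] <- cpc
  }

  from <- character(0); to <- character(0)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      i <- genes[a]; j <- genes[b]
      if (j %in% pc[[i]] && i %in% pc[[j]]) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  structure(list(nodes = genes,
                 edges = tibble::tibble(from = from, to = to),
                 sepsets = sepsets),
            class = "bn_skeleton")
}

#' @export
print.bn_skeleton <- function(x, ...) {
  cat(sprintf("<bn_skeleton> %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# decomposable local score from the MLE covariance matrix (denominator n):
# maximized Gaussian log-likelihood of node given parents minus
# (|parents| + 2)/2 * log(n)
local_bic <- function(S, n, node, parents, ridge) {
  if (length(parents)) {
    Spp <- S[parents, parents, drop = FALSE]
    Spv <- S[parents, node, drop = FALSE]
    beta <- tryCatch(solve(Spp, Spv),
                     error = function(e)
                       solve(Spp + diag(ridge, length(parents)), Spv))
    sigma2 <- S[node, node] - sum(Spv * beta)
  } else {
    sigma2 <- S[node, node]
  }
  sigma2 <- max(sigma2, 1e-12)
  -n / 2 * (log(2 * pi) + log(sigma2) + 1) -
    (length(parents) + 2) / 2 * log(n)
}

#' Gaussian BIC of a directed network
#'
#' Decomposable score: per node, the maximized Gaussian log-likelihood of
#' the node's linear regression on its parents (with intercept) minus
#' `(|parents| + 2)/2 * log(n)` penalty (coefficients + intercept +
#' residual variance). Higher is better.
#'
#' @param data Numeric matrix, genes x samples.
#' @param dag A [directed_network()] whose nodes are in `data`.
#' @return The total score (numeric scalar).
#' @export
gaussian_bic <- function(data, dag) {
  if (!all(dag$nodes %in% rownames(data))) {
    abort("all dag nodes must be rows of `data`")
  }
  n <- ncol(data)
  x <- data[dag$nodes, , drop = FALSE]
  xc <- x - rowMeans(x)
  S <- tcrossprod(xc) / n
  sum(vapply(dag$nodes, function(v) {
    local_bic(S, n, v, dag$edges$from[dag$edges$to == v], 1e-8)
  }, numeric(1)))
}

# does a path v ~> u exist in adjacency list `ch` (children lists)?
reaches <- function(ch, v, u) {
  stack <- ch[[v]]
  seen <- character(0)
  while (length(stack)) {
    w <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (w == u) return(TRUE)
    if (!(w %in% seen)) {
      seen <- c(seen, w)
      stack <- c(stack, ch[[w]])
    }
  }
  FALSE
}

#' Score-based orientation by greedy hill climbing
#'
#' Greedy search from the empty graph over add / delete / reverse
#' operators, with additions restricted to skeleton pairs and all states
#' acyclic. Each iteration applies the single best score-improving move;
#' ties are broken deterministically by lexicographic
#' (operator, source id, target id). Stops when no move improves the
#' Gaussian BIC.
#'
#' @param data Numeric matrix, genes x samples.
#' @param skeleton A [mmpc_skeleton()] result over the same genes.
#' @param config A [bn_config()].
#' @return A [directed_network()] with its `score`; the attribute
#'   `converged` is `FALSE` if `max_iterations` was hit (with a warning).
#' @export
hill_climb <- function(data, skeleton, config = bn_config()) {
  genes <- skeleton$nodes
  if (!all(genes %in% rownames(data))) {
    abort("skeleton nodes must be rows of `data`")
  }
  n <- ncol(data)
  x <- data[genes, , drop = FALSE]
  xc <- x - rowMeans(x)
  S <- tcrossprod(xc) / n

  cache <- new.env(parent = emptyenv())
  score_of <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "~")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- local_bic(S, n, v, pa, config$ridge)
      cache[[key]] <- got
    }
    got
  }

  parents <- setNames(replicate(length(genes), character(0),
                                simplify = FALSE), genes)
  children <- setNames(replicate(length(genes), character(0),
                                 simplify = FALSE), genes)
  node_scores <- setNames(vapply(genes, score_of, numeric(1),
                                 pa = character(0)), genes)

  skel_pairs <- skeleton$edges
  tol <- 1e-10
  converged <- FALSE
  iter <- 0
  while (iter < config$max_iterations) {
    iter <- iter + 1
    best <- NULL  # list(op, from, to, delta)
    consider <- function(op, from, to, delta) {
      if (delta <= tol) return()
      if (is.null(best) ||
          delta > best$delta + tol ||
          (abs(delta - best$delta) <= tol &&
           paste(op, from, to) < paste(best$op, best$from, best$to))) {
        best <<- list(op = op, from = from, to = to, delta = delta)
      }
    }
    # additions (skeleton pairs only, both directions)
    if (nrow(skel_pairs)) {
      for (k in seq_len(nrow(skel_pairs))) {
        a <- skel_pairs$from[k]; b <- skel_pairs$to[k]
        for (dir in list(c(a, b), c(b, a))) {
          u <- dir[1]; v <- dir[2]
          if (u %in% parents[[v]]) next
          if (reaches(children, v, u)) next  # would create a cycle
          delta <- score_of(v, c(parents[[v]], u)) - node_scores[[v]]
          consider("add", u, v, delta)
        }
      }
    }
    # deletions and reversals of current edges
    for (v in genes) {
      for (u in parents[[v]]) {
        delta_del <- score_of(v, setdiff(parents[[v]], u)) - node_scores[[v]]
        consider("delete", u, v, delta_del)
        # reverse u -> v to v -> u
        children[[u]] <- setdiff(children[[u]], v)
        cyc <- reaches(children, u, v)
        children[[u]] <- c(children[[u]], v)
        if (!cyc) {
          delta <- delta_del +
            score_of(u, c(parents[[u]], v)) - node_scores[[u]]
          consider("reverse", u, v, delta)
        }
      }
    }
    if (is.null(best)) { converged <- TRUE; break }
    u <- best$from; v <- best$to
    if (best$op == "add") {
      parents[[v]] <- c(parents[[v]], u)
      children[[u]] <- c(children[[u]], v)
      node_scores[[v]] <- score_of(v, parents[[v]])
    } else if (best$op == "delete") {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      node_scores[[v]] <- score_of(v, parents[[v]])
    } else {
      parents[[v]] <- setdiff(parents[[v]], u)
      children[[u]] <- setdiff(children[[u]], v)
      parents[[u]] <- c(parents[[u]], v)
      children[[v]] <- c(children[[v]], u)
      node_scores[[v]] <- score_of(v, parents[[v]])
      node_scores[[u]] <- score_of(u, parents[[u]])
    }
  }
  if (!converged) {
    warn(sprintf("hill climbing stopped at max_iterations = %d",
                 config$max_iterations))
  }
  edges <- purrr::map_dfr(genes, function(v) {
    if (length(parents[[v]])) {
      tibble::tibble(from = sort(parents[[v]]), to = v)
    } else {
      tibble::tibble(from = character(0), to = character(0))
    }
  })
  net <- directed_network(genes, edges, score = sum(node_scores))
  attr(net, "converged") <- converged
  net
}
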