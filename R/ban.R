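#' Size of a gene's k-step network neighborhood
#'
#' Number of nodes reachable from `gene` within `steps` edges, treating
#' edges as undirected and including the gene itself.
#'
#' @param graph A [directed_network()].
#' @param gene Gene id (must be a node).
#' @param steps Neighborhood step size.
#' @return Integer neighborhood size.
#' @export
ego_size <- function(graph, gene, steps = 3) {
  if (!gene %in% graph$nodes) abort(sprintf("gene %s not in graph", gene))
  g <- as_igraph(graph)
  as.integer(igraph::ego_size(g, order = steps, nodes = gene, mode = "all"))
}

# ego sizes for all nodes at once (single igraph call)
ego_sizes_all <- function(graph, steps = 3) {
  g <- as_igraph(graph)
  setNames(as.integer(igraph::ego_size(g, order = steps, mode = "all")),
           igraph::V(g)$name)
}

# the set of genes in the k-step undirected neighborhood (incl. self)
ego_members <- function(graph, steps = 3) {
  g <- as_igraph(graph)
  eg <- igraph::ego(g, order = steps, mode = "all")
  setNames(lapply(eg, function(v) v$name), igraph::V(g)$name)
}

#' Prune weakly connected candidate genes
#'
#' Stage 1 removes genes whose neighborhood size is at most 2 (unconnected
#' or connected to a single neighbor). Stage 2 computes the mean and sample
#' SD of the remaining sizes and removes genes whose size is smaller than
#' mean - SD.
#'
#' @param size_table Named integer vector: gene -> neighborhood size.
#' @return Character vector of retained gene ids (empty, with a warning,
#'   if everything is pruned).
#' @export
prune_candidates <- function(size_table) {
  if (!length(size_table)) abort("`size_table` must be nonempty")
  stage1 <- size_table[size_table > 2]
  if (!length(stage1)) {
    warn("all genes pruned (no gene has neighborhood size > 2)")
    return(character(0))
  }
  thr <- mean(stage1) - sd(stage1)
  if (is.na(thr)) thr <- -Inf  # a single gene: sample SD undefined
  names(stage1)[stage1 >= thr]
}

#' Hypergeometric BAN p-value
#'
#' Upper-tail probability `P(X >= overlap)` for X hypergeometric with `m`
#' bone genes, `n_bg` non-bone genes in the universe, and `k` draws (the
#' neighborhood size) — the `q = overlap - 1, lower.tail = FALSE`
#' convention.
#'
#' @param overlap Bone genes observed in the neighborhood.
#' @param m Bone genes in the universe.
#' @param n_bg Non-bone genes in the universe.
#' @param k Neighborhood size (draws).
#' @return The p-value.
#' @export
ban_pvalue <- function(overlap, m, n_bg, k) {
  assert_count(overlap, "overlap", min = 0)
  assert_count(m, "m", min = 0)
  assert_count(n_bg, "n_bg", min = 0)
  assert_count(k, "k", min = 0)
  if (overlap > min(k, m) || k > m + n_bg) {
    abort("impossible counts: need overlap <= min(k, m) and k <= m + n_bg")
  }
  phyper(overlap - 1, m, n_bg, k, lower.tail = FALSE)
}

#' BAN analysis over a collection of module networks
#'
#' Per network set: pools all module DAGs, computes every gene's 3-step
#' undirected neighborhood size, applies [prune_candidates()], and for each
#' retained gene tests whether its neighborhood is enriched for known bone
#' genes with [ban_pvalue()], using `m` = bone genes among the network
#' set's genes and `n_bg` = pre-pruning universe size minus `m`. Genes at
#' nominal p <= `p_threshold` are flagged as BANs.
#'
#' @param networks Named list (by network label) of lists of
#'   [directed_network()] objects, one per module; module names are taken
#'   from the inner list names.
#' @param bone Character vector of known bone gene ids.
#' @param universe_size_pre_prune Optional named integer vector (by network
#'   label) giving the number of genes in the networks prior to pruning;
#'   defaults to the pooled node count of each set.
#' @param steps Neighborhood step size.
#' @param p_threshold Nominal BAN threshold.
#' @return Tibble with columns `gene, network, module, k, overlap, m, n_bg,
#'   p_value, is_ban`.
#' @export
run_ban <- function(networks, bone, universe_size_pre_prune = NULL,
                    steps = 3, p_threshold = 0.05) {
  if (!length(networks)) abort("`networks` must be nonempty")
  if (!length(bone)) abort("bone gene list must be nonempty")
  if (is.null(names(networks))) names(networks) <- paste0("net", seq_along(networks))
  purrr::imap_dfr(networks, function(mods, label) {
    if (!length(mods)) abort(sprintf("network set %s is empty", label))
    if (is.null(names(mods))) names(mods) <- paste0("mod", seq_along(mods))
    all_nodes <- unlist(lapply(mods, `[[`, "nodes"), use.names = FALSE)
    if (anyDuplicated(all_nodes)) {
      abort(sprintf("gene(s) appear in multiple modules of %s", label))
    }
    pooled <- directed_network(
      all_nodes,
      dplyr::bind_rows(lapply(mods, function(m) m$edges[c("from", "to")])),
      check_acyclic = FALSE
    )
    module_of <- rep(names(mods), vapply(mods, function(m) length(m$nodes),
                                         integer(1)))
    names(module_of) <- all_nodes
    sizes <- ego_sizes_all(pooled, steps)
    members <- ego_members(pooled, steps)
    retained <- prune_candidates(sizes)

    m <- sum(bone %in% all_nodes)
    universe <- if (is.null(universe_size_pre_prune)) {
      length(all_nodes)
    } else {
      universe_size_pre_prune[[label]]
    }
    n_bg <- universe - m
    k_vec <- unname(sizes[retained])
    ov_vec <- vapply(members[retained], function(nb) sum(nb %in% bone),
                     integer(1))
    p_vec <- vapply(seq_along(retained), function(i) {
      ban_pvalue(ov_vec[i], m, n_bg, k_vec[i])
    }, numeric(1))
    tibble::tibble(
      gene = retained,
      network = label,
      module = unname(module_of[retained]),
      k = k_vec,
      overlap = unname(ov_vec),
      m = m,
      n_bg = n_bg,
      p_value = p_vec,
      is_ban = p_vec <= p_threshold
    )
  })
}

#' Connectivity comparison of bone vs non-bone genes
#'
#' One-sided Wilcoxon rank-sum test that bone genes have larger network
#' neighborhoods than non-bone genes (normal approximation with tie
#' correction).
#'
#' @param size_table Named numeric vector: gene -> neighborhood size.
#' @param bone_flags Named logical vector over the same genes.
#' @return The one-sided p-value.
#' @export
connectivity_test <- function(size_table, bone_flags) {
  bone_flags <- bone_flags[names(size_table)]
  x <- size_table[bone_flags]
  y <- size_table[!bone_flags]
  if (!length(x) || !length(y)) abort("both classes must be nonempty")
  if (length(unique(size_table)) == 1) return(1)  # no separation possible
  suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  )
}
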