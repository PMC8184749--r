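#' Construct a directed network
#'
#' Light-weight container for a directed (acyclic) gene network: the learned
#' Bayesian networks, the planted simulation DAGs, and the inputs to the
#' BAN neighborhood analysis all use this class.
#'
#' @param nodes Character vector of node (gene) identifiers.
#' @param edges A data frame with columns `from` and `to` (and optionally
#'   `weight`); both must be subsets of `nodes`. Zero-row edge sets are
#'   allowed (the empty network).
#' @param score Optional numeric network score (Gaussian BIC for learned
#'   networks).
#' @param check_acyclic If `TRUE` (default) reject cyclic edge sets with an
#'   error of class `netban_cyclic_error`.
#'
#' @return An object of class `bn_network`: a list with elements `nodes`,
#'   `edges` (tibble) and `score`.
#' @export
#' @examples
#' directed_network(c("a", "b", "c"),
#'                  data.frame(from = c("a", "b"), to = c("b", "c")))
directed_network <- function(nodes, edges = NULL, score = NA_real_,
                             check_acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node ids in `nodes`")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      abort("`edges` must have columns `from` and `to`")
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad <- setdiff(c(edges$from, edges$to), nodes)
    if (length(bad)) abort(paste0("edge endpoints not in `nodes`: ",
                                  paste(head(bad, 5), collapse = ", ")))
    if (any(edges$from == edges$to)) abort("self-edges are not allowed")
  }
  net <- structure(list(nodes = nodes, edges = edges, score = score),
                   class = "bn_network")
  if (check_acyclic && is.null(topological_order(net))) {
    abort("edge set contains a directed cycle", class = "netban_cyclic_error")
  }
  net
}

#' Topological order of a directed network
#'
#' @param net A `bn_network`.
#' @return Character vector of nodes in topological order, or `NULL` if the
#'   graph is cyclic.
#' @export
topological_order <- function(net) {
  nodes <- net$nodes
  if (!nrow(net$edges)) return(nodes)
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  from <- idx[net$edges$from]
  to <- idx[net$edges$to]
  indeg <- tabulate(to, nbins = n)
  adj <- split(to, factor(from, levels = seq_len(n)))
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    # smallest index first: deterministic order
    v <- min(queue)
    queue <- queue[queue != v]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) return(NULL)
  nodes[order]
}

as_igraph <- function(net, directed = TRUE) {
  igraph::graph_from_data_frame(net$edges, directed = directed,
                                vertices = data.frame(name = net$nodes))
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("<bn_network> %d nodes, %d edges", length(x$nodes),
              nrow(x$edges)))
  if (is.finite(x$score)) cat(sprintf(", score %.4f", x$score))
  cat("\n")
  invisible(x)
}
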