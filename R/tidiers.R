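#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a learned network into its edge list
#' @param x A `bn_network`.
#' @param ... Unused.
#' @return Tibble with `from`, `to` (plus `weight` if present).
#' @exportS3Method generics::tidy
tidy.bn_network <- function(x, ...) {
  x$edges
}

#' One-row summary of a learned network
#' @param x A `bn_network`.
#' @param ... Unused.
#' @return Tibble with `n_nodes`, `n_edges`, `score`.
#' @exportS3Method generics::glance
glance.bn_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 score = x$score)
}

#' Tidy module assignments
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `network`, `module`.
#' @exportS3Method generics::tidy
tidy.module_partition <- function(x, ...) {
  tibble::tibble(gene_id = names(x$module_of_gene),
                 network = x$network_label,
                 module = unname(x$module_of_gene))
}

#' One-row summary of a module partition
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble with `network`, `n_modules`, `n_genes`, `n_unassigned`,
#'   `largest_module`.
#' @exportS3Method generics::glance
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    network = x$network_label,
    n_modules = length(x$module_sizes),
    n_genes = length(x$module_of_gene),
    n_unassigned = sum(x$module_of_gene == "unassigned"),
    largest_module = if (length(x$module_sizes)) max(x$module_sizes) else 0L
  )
}

#' Tidy colocalization posteriors
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Tibble with `hypothesis` (H0..H4) and `posterior`.
#' @exportS3Method generics::tidy
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = paste0("H", 0:4),
                 posterior = c(x$pph0, x$pph1, x$pph2, x$pph3, x$pph4))
}

#' One-row summary of a colocalization result
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Tibble with `n_snps`, `pph4`, `colocalizing`.
#' @exportS3Method generics::glance
glance.coloc_result <- function(x, ...) {
  tibble::tibble(n_snps = x$n_snps, pph4 = x$pph4,
                 colocalizing = x$colocalizing)
}
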