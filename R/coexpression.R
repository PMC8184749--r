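#' Signed weighted adjacency
#'
#' Computes the signed soft-thresholded adjacency
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power` from Pearson correlations, with
#' a zero diagonal. Anti-correlated genes get adjacency near 0, perfectly
#' correlated genes near 1.
#'
#' @param expr Numeric matrix, genes x samples (at least 3 samples).
#' @param power Soft-thresholding exponent (beta); 4 is the package
#'   default, 5 is conventional for male-only networks.
#' @return List of class `adjacency` with elements `a` (matrix), `power`
#'   and `gene_ids`.
#' @export
signed_adjacency <- function(expr, power = 4) {
  if (ncol(expr) < 3) abort("need at least 3 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene(s): ",
                 paste(head(rownames(expr)[sds == 0], 5), collapse = ", ")))
  }
  a <- ((1 + cor(t(expr))) / 2)^power
  diag(a) <- 0
  structure(list(a = a, power = power, gene_ids = rownames(expr)),
            class = "adjacency")
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over third genes and `k_i` is the connectivity
#' `sum_u a_iu`; the diagonal is 1. Gene pairs that are strongly connected
#' and share neighbors get similarity near 1.
#'
#' @param adj An [signed_adjacency()] result.
#' @return List of class `tom` with elements `tom` and `gene_ids`.
#' @export
tom_similarity <- function(adj) {
  if (!inherits(adj, "adjacency")) abort("`adj` must come from signed_adjacency()")
  a <- adj$a
  l <- a %*% a          # diag(a)=0, so the u = i, j terms vanish
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  structure(list(tom = tom, gene_ids = adj$gene_ids), class = "tom")
}

# First principal component of the (gene-standardized) module submatrix,
# unit norm, sign-aligned with the module mean profile (ties broken toward
# the first gene in id order).
eigengene_of <- function(expr, genes) {
  xs <- t(expr[genes, , drop = FALSE])       # samples x genes
  xs <- scale(xs)
  u <- svd(xs, nu = 1, nv = 0)$u[, 1]
  ref <- rowMeans(xs)
  s <- sum(u * ref)
  if (abs(s) < 1e-12) s <- sum(u * xs[, 1])
  if (abs(s) < 1e-12) s <- 1
  u * sign(s)
}

#' Module eigengenes
#'
#' Per module, the first principal component of the gene-standardized
#' expression submatrix (unit norm over samples), sign-aligned so its
#' correlation with the module's mean expression profile is nonnegative.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param partition A `module_partition` or a named gene -> module label
#'   vector; the label `"unassigned"` is skipped.
#' @return Numeric matrix, samples x modules.
#' @export
module_eigengenes <- function(expr, partition) {
  map <- if (inherits(partition, "module_partition")) {
    partition$module_of_gene
  } else {
    partition
  }
  map <- map[intersect(names(map), rownames(expr))]
  mods <- setdiff(unique(map), "unassigned")
  if (!length(mods)) {
    return(matrix(numeric(0), ncol(expr), 0,
                  dimnames = list(colnames(expr), character(0))))
  }
  me <- vapply(mods, function(m) eigengene_of(expr, names(map)[map == m]),
               numeric(ncol(expr)))
  dimnames(me) <- list(colnames(expr), mods)
  me
}

#' Detect co-expression modules from topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than `min_module_size` are
#' labelled `"unassigned"`. Modules whose eigengenes are closer than
#' `merge_height` (dissimilarity `1 - cor`) are then merged iteratively,
#' closest pair first, recomputing eigengenes after every merge. Final
#' labels are `M1, M2, ...` by decreasing module size.
#'
#' @param tom A [tom_similarity()] result.
#' @param expr Numeric matrix, genes x samples, same gene set as `tom`.
#' @param min_module_size Smallest cluster kept as a module.
#' @param merge_height Eigengene dissimilarity below which modules merge.
#' @param cut_height Static tree-cut height. The default places the cut at
#'   the midpoint of the largest gap among the upper half of the tree's
#'   merge heights, which separates tight clusters from the noise-level
#'   merges above them without a tuned constant.
#' @param network_label Label for the network set (e.g. `"combined"`).
#' @return An object of class `module_partition`: list with
#'   `module_of_gene` (named vector), `eigengenes` (samples x modules),
#'   `module_sizes`, `network_label`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 30,
                           merge_height = 0.15, cut_height = NULL,
                           network_label = "combined") {
  if (!inherits(tom, "tom")) abort("`tom` must come from tom_similarity()")
  genes <- tom$gene_ids
  if (!setequal(genes, rownames(expr))) {
    abort("`tom` and `expr` must share the same gene set")
  }
  expr <- expr[genes, , drop = FALSE]
  if (length(genes) < min_module_size) {
    warn("fewer genes than `min_module_size`; all genes unassigned")
    map <- setNames(rep("unassigned", length(genes)), genes)
    return(new_module_partition(map, expr, network_label))
  }
  d <- 1 - tom$tom
  h <- hclust(as.dist(d), method = "average")
  if (is.null(cut_height)) cut_height <- default_cut_height(h$height)
  cl <- cutree(h, h = cut_height)
  map <- setNames(paste0("c", cl), genes)
  sizes <- table(map)
  map[map %in% names(sizes)[sizes < min_module_size]] <- "unassigned"

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(map), "unassigned")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, map)
    dme <- 1 - cor(me)
    diag(dme) <- Inf
    if (min(dme) >= merge_height) break
    ij <- which(dme == min(dme), arr.ind = TRUE)[1, ]
    keep <- colnames(me)[min(ij)]
    drop <- colnames(me)[max(ij)]
    map[map == drop] <- keep
  }
  new_module_partition(map, expr, network_label)
}

# Default static cut: midpoint of the largest gap among the upper half of
# the merge heights; degenerate trees (all heights equal) collapse to one
# cluster.
default_cut_height <- function(heights) {
  hs <- sort(heights)
  if (length(hs) < 3 || max(hs) - min(hs) < 1e-8) return(max(hs))
  top <- hs[hs >= median(hs)]
  gaps <- diff(top)
  i <- which.max(gaps)
  (top[i] + top[i + 1]) / 2
}

new_module_partition <- function(map, expr, network_label) {
  mods <- setdiff(unique(map), "unassigned")
  if (!length(mods)) {
    me <- matrix(numeric(0), ncol(expr), 0,
                 dimnames = list(colnames(expr), character(0)))
    return(structure(list(network_label = network_label,
                          module_of_gene = map, eigengenes = me,
                          module_sizes = setNames(integer(0), character(0))),
                     class = "module_partition"))
  }
  sizes <- vapply(mods, function(m) sum(map == m), integer(1))
  ord <- order(-sizes, mods)
  relabel <- setNames(paste0("M", seq_along(mods)), mods[ord])
  out <- map
  out[map != "unassigned"] <- relabel[map[map != "unassigned"]]
  me <- module_eigengenes(expr, out)
  if (ncol(me)) me <- me[, paste0("M", seq_len(ncol(me))), drop = FALSE]
  structure(list(
    network_label = network_label,
    module_of_gene = out,
    eigengenes = me,
    module_sizes = setNames(sizes[ord], paste0("M", seq_along(mods)))
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> network %s: %d modules, %d/%d genes assigned\n",
              x$network_label, length(x$module_sizes),
              sum(x$module_of_gene != "unassigned"),
              length(x$module_of_gene)))
  invisible(x)
}

#' Eigengene-trait association
#'
#' Spearman rank correlation of each module eigengene with each trait, with
#' asymptotic two-sided p-values and pairwise deletion of missing trait
#' values. P-values are nominal (no multiplicity adjustment).
#'
#' @param eigengenes Numeric matrix, samples x modules.
#' @param traits Numeric matrix or data frame, samples x traits.
#' @return Tibble with columns `module, trait, rho, p, n, estimable`; pairs
#'   with fewer than 4 complete observations are flagged not estimable.
#' @export
eigengene_trait_assoc <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(eigengenes)) {
    abort("`eigengenes` and `traits` must share samples")
  }
  if (is.null(colnames(traits))) {
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  }
  grid <- tidyr::expand_grid(module = colnames(eigengenes),
                             trait = colnames(traits))
  res <- purrr::pmap_dfr(grid, function(module, trait) {
    x <- eigengenes[, module]
    y <- traits[, trait]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 4) {
      return(tibble::tibble(module = module, trait = trait,
                            rho = NA_real_, p = NA_real_,
                            n = sum(ok), estimable = FALSE))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    tibble::tibble(module = module, trait = trait,
                   rho = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok), estimable = TRUE)
  })
  res
}
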