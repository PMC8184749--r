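#' Expression-level gene filter
#'
#' Retains genes with strictly more than `min_reads` reads and strictly
#' more than `min_tpm` TPM in strictly more than `min_fraction` of samples
#' (both conditions evaluated jointly per sample).
#'
#' @param counts A [count_matrix()]; must carry TPM if `min_tpm > 0`.
#' @param min_reads Read-count threshold (exclusive).
#' @param min_tpm TPM threshold (exclusive); set to 0 to filter on reads
#'   alone.
#' @param min_fraction Fraction-of-samples threshold (exclusive).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_reads = 6, min_tpm = 0.1,
                             min_fraction = 0.2) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a count_matrix")
  assert_prob(min_fraction, "min_fraction")
  cm <- counts$counts
  ok <- cm > min_reads
  if (min_tpm > 0) {
    if (is.null(counts$tpm)) {
      abort("TPM values required when `min_tpm` > 0; supply them or gene lengths")
    }
    ok <- ok & (counts$tpm > min_tpm)
  }
  n <- ncol(cm)
  keep <- rowSums(ok) > min_fraction * n
  rownames(cm)[keep]
}

#' Network-stage gene filter
#'
#' Removes genes with fewer than 10 reads in more than 90% of samples, and
#' genes not located on an autosome or the X chromosome. Genes missing from
#' the annotation are excluded with a warning.
#'
#' @param counts A [count_matrix()].
#' @param gene_table Data frame with `gene_id` and `chrom` columns.
#' @return Character vector of retained gene ids.
#' @export
filter_network_genes <- function(counts, gene_table) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a count_matrix")
  if (!all(c("gene_id", "chrom") %in% names(gene_table))) {
    abort("`gene_table` must have columns `gene_id` and `chrom`")
  }
  cm <- counts$counts
  n <- ncol(cm)
  low <- rowSums(cm < 10) > 0.9 * n
  keep <- rownames(cm)[!low]
  missing <- setdiff(keep, gene_table$gene_id)
  if (length(missing)) {
    warn(sprintf("%d gene(s) missing from annotation; excluded (e.g. %s)",
                 length(missing), missing[1]))
    keep <- setdiff(keep, missing)
  }
  chrom <- gene_table$chrom[match(keep, gene_table$gene_id)]
  keep[is_autosome_or_x(chrom)]
}

#' Normalize counts and residualize nuisance covariates
#'
#' Applies a log2(CPM + 1) transform, then fits a per-gene linear model on
#' the union of `adjust_for` and `protect` covariates and subtracts the
#' fitted contribution of the `adjust_for` terms only, so protected
#' biological signal (e.g. sex) is retained while batch structure is
#' removed.
#'
#' @param counts A [count_matrix()].
#' @param covariates Data frame with `sample_id` plus covariate columns.
#' @param adjust_for Covariate names whose fitted effects are subtracted.
#' @param protect Covariate names kept in the model but not subtracted.
#' @return Numeric matrix (genes x samples) of adjusted log2(CPM + 1)
#'   expression.
#' @export
normalize_adjust <- function(counts, covariates, adjust_for = "batch",
                             protect = character()) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a count_matrix")
  if (length(intersect(adjust_for, protect))) {
    abort("`adjust_for` and `protect` must be disjoint")
  }
  cm <- counts$counts
  covariates <- as.data.frame(covariates)
  if (!all(counts$sample_ids %in% covariates$sample_id)) {
    abort("every sample must appear in `covariates`")
  }
  covariates <- covariates[match(counts$sample_ids, covariates$sample_id), ,
                           drop = FALSE]
  vars <- c(adjust_for, protect)
  missing_vars <- setdiff(vars, names(covariates))
  if (length(missing_vars)) {
    abort(paste0("covariate(s) not found: ", paste(missing_vars, collapse = ", ")))
  }

  cpm <- sweep(cm, 2, colSums(cm), "/") * 1e6
  y <- log2(cpm + 1)
  if (!length(vars)) return(y)

  fml <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  X <- model.matrix(fml, data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste0("singular design: collinear covariate term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  # per-gene OLS, all genes at once: coef is (terms x genes)
  coef <- qr.coef(qrX, t(y))
  adjust_cols <- which(attr(X, "assign") %in%
                         match(adjust_for, vars))
  if (!length(adjust_cols)) return(y)
  fitted_adj <- X[, adjust_cols, drop = FALSE] %*%
    coef[adjust_cols, , drop = FALSE]
  y - t(fitted_adj)
}
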