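#' Read a count matrix from TSV
#'
#' Expects a header row, first column `gene_id`, remaining columns one per
#' sample with integer cells; an optional parallel TPM TSV of identical
#' shape can be supplied.
#'
#' @param path Path to the counts TSV.
#' @param tpm_path Optional path to the TPM TSV.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, tpm_path = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  tpm <- NULL
  if (!is.null(tpm_path)) {
    tf <- readr::read_tsv(tpm_path, show_col_types = FALSE)
    tpm <- as.matrix(tf[-1])
    rownames(tpm) <- tf$gene_id
    tpm <- tpm[rownames(m), colnames(m), drop = FALSE]
  }
  count_matrix(m, tpm)
}

#' Write a count matrix (and optional TPM) to TSV
#' @param cm A [count_matrix()].
#' @param path Counts TSV path.
#' @param tpm_path Optional TPM TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path, tpm_path = NULL) {
  as_df <- function(m) {
    tibble::as_tibble(m, rownames = "gene_id")
  }
  readr::write_tsv(as_df(cm$counts), path)
  if (!is.null(tpm_path) && !is.null(cm$tpm)) {
    readr::write_tsv(as_df(cm$tpm), tpm_path)
  }
  invisible(path)
}

#' Read a known-bone-gene list
#'
#' Newline-delimited gene ids; `#` comments and blank lines are skipped.
#'
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_bone_gene_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- lines[nzchar(lines)]
  if (!length(ids)) abort("bone gene list is empty")
  if (anyDuplicated(ids)) ids <- unique(ids)
  ids
}

#' Read / write per-SNP summary statistics
#'
#' TSV with header `snp, chr, bp, beta, se, maf, n`.
#' @param path File path.
#' @return A summary-statistics tibble.
#' @export
read_assoc_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("chr" %in% names(df)) df$chr <- as.character(df$chr)
  if ("snp" %in% names(df)) df$snp <- as.character(df$snp)
  check_assoc_stats(df, path)
}

#' @rdname read_assoc_tsv
#' @param stats Summary-statistics tibble to write.
#' @export
write_assoc_tsv <- function(stats, path) {
  readr::write_tsv(check_assoc_stats(stats, "stats"), path)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#' @param path File path.
#' @return Tibble `chrom, start, end` (+ `label` if a 4th column exists).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(df) <- c("chrom", "start", "end", "label")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom, start, end` (+ optional `label`).
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Write module assignments to TSV (`gene_id, network, module`)
#' @param partition A `module_partition`.
#' @param path File path.
#' @export
write_partition_tsv <- function(partition, path) {
  readr::write_tsv(tibble::tibble(
    gene_id = names(partition$module_of_gene),
    network = partition$network_label,
    module = unname(partition$module_of_gene)
  ), path)
  invisible(path)
}

#' Write learned networks as an edge-list TSV (`from, to, network, module`)
#' @param networks Named list (network label) of named lists (module) of
#'   [directed_network()] objects.
#' @param path File path.
#' @export
write_networks_tsv <- function(networks, path) {
  rows <- purrr::imap_dfr(networks, function(mods, label) {
    purrr::imap_dfr(mods, function(net, mod) {
      if (!nrow(net$edges)) return(NULL)
      dplyr::mutate(net$edges[c("from", "to")], network = label,
                    module = mod)
    })
  })
  readr::write_tsv(rows, path)
  invisible(path)
}
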