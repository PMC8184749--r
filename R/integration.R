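#' Flag genes near GWAS lead SNPs
#'
#' A gene is flagged when the minimum distance from its interval (0-based,
#' half-open) to any lead SNP position is at most `max_dist` (0 for an
#' overlapping lead; the boundary is inclusive).
#'
#' @param genes Tibble with `gene_id, chrom, start, end`.
#' @param leads Tibble with `snp_id, chrom, pos` (may be empty).
#' @param max_dist Distance threshold in bp.
#' @return Named logical vector over `genes$gene_id`.
#' @export
genes_near_leads <- function(genes, leads, max_dist = 1e6) {
  if (nrow(leads) == 0) {
    return(setNames(rep(FALSE, nrow(genes)), genes$gene_id))
  }
  shared <- intersect(unique(genes$chrom), unique(leads$chrom))
  if (!length(shared)) {
    abort(paste0(
      "chromosome naming mismatch: genes use {",
      paste(sort(unique(genes$chrom)), collapse = ", "), "}, leads use {",
      paste(sort(unique(leads$chrom)), collapse = ", "), "}"))
  }
  flag <- vapply(seq_len(nrow(genes)), function(i) {
    p <- leads$pos[leads$chrom == genes$chrom[i]]
    if (!length(p)) return(FALSE)
    last <- genes$end[i] - 1  # last base of the half-open interval
    d <- pmax(0, genes$start[i] - p, p - last)
    min(d) <= max_dist
  }, logical(1))
  setNames(flag, genes$gene_id)
}

#' Enrichment odds ratio and Fisher exact p
#'
#' Cross-product (sample) odds ratio `(a*d)/(b*c)` for the 2x2 table
#' `[[a, b], [c, d]]` and the two-sided Fisher exact p-value (sum of table
#' probabilities at most the observed table's probability).
#'
#' @param a,b,c,d Nonnegative cell counts; `a` is the doubly-positive cell.
#' @return Tibble with `odds_ratio`, `p`, and `estimable` (`FALSE` with
#'   `p = 1` when a margin is zero; an infinite OR from an empty
#'   off-diagonal is reported as `Inf`).
#' @export
fisher_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) {
    abort("counts must be nonnegative with a positive total")
  }
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  margins <- c(rowSums(tab), colSums(tab))
  if (any(margins == 0)) {
    return(tibble::tibble(odds_ratio = NA_real_, p = 1, estimable = FALSE))
  }
  or <- (a * d) / (b * c)  # Inf when b*c == 0 with a*d > 0
  p <- fisher.test(tab)$p.value
  tibble::tibble(odds_ratio = or, p = p, estimable = is.finite(or))
}

#' Permutation null for locus / lead-SNP overlap
#'
#' Counts how many loci contain at least one lead SNP, then compares
#' against a null built by placing length-matched intervals uniformly at
#' random on the supplied chromosomes (chromosome chosen proportional to
#' its placeable length) `n_perm` times. The percentile uses the <=
#' convention: `100 * (# null draws with count <= observed) / n_perm`.
#'
#' @param loci Tibble with `chrom, start, end` (0-based half-open).
#' @param leads Tibble with `chrom, pos`.
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `percentile`, and the `null_counts`
#'   vector.
#' @export
interval_overlap_null <- function(loci, leads, chrom_sizes, n_perm = 1000,
                                  seed = 1) {
  if (!nrow(loci)) abort("`loci` must be nonempty")
  lens <- loci$end - loci$start
  if (any(lens > max(chrom_sizes))) {
    abort("a locus is longer than every chromosome")
  }
  count_overlaps <- function(chrom, start, end) {
    sum(vapply(seq_along(chrom), function(i) {
      any(leads$chrom == chrom[i] & leads$pos >= start[i] &
            leads$pos < end[i])
    }, logical(1)))
  }
  observed <- count_overlaps(loci$chrom, loci$start, loci$end)
  with_seed(seed, {
    null_counts <- vapply(seq_len(n_perm), function(r) {
      ch <- character(length(lens)); st <- numeric(length(lens))
      for (i in seq_along(lens)) {
        fits <- chrom_sizes[chrom_sizes >= lens[i]]
        placeable <- fits - lens[i] + 1
        ch[i] <- sample(names(fits), 1, prob = placeable)
        st[i] <- floor(runif(1, 0, chrom_sizes[[ch[i]]] - lens[i] + 1))
      }
      count_overlaps(ch, st, st + lens)
    }, numeric(1))
    list(observed = observed,
         percentile = 100 * mean(null_counts <= observed),
         null_counts = null_counts)
  })
}

#' Ranked candidate-gene report
#'
#' Joins the BAN table, per-gene colocalization results and GWAS-proximity
#' flags; candidate genes are those that are a BAN, lie near a lead SNP,
#' and have a colocalizing eQTL. Rows are sorted by PPH4 (descending) then
#' BAN p-value (ascending), and all intermediate columns are kept for
#' audit.
#'
#' @param ban BAN tibble from [run_ban()].
#' @param coloc Tibble with one row per gene: `gene, pph0..pph4, n_snps,
#'   colocalizing` (genes without a coloc test may be absent).
#' @param proximity Named logical vector gene -> near-lead flag.
#' @return Tibble of all BAN-table genes with joined evidence and a
#'   `candidate` flag; candidates sort first.
#' @export
candidate_report <- function(ban, coloc, proximity) {
  prox <- tibble::tibble(gene = names(proximity),
                         near_lead = unname(proximity))
  out <- ban |>
    dplyr::left_join(prox, by = "gene") |>
    dplyr::left_join(coloc, by = "gene") |>
    dplyr::mutate(
      near_lead = dplyr::coalesce(.data$near_lead, FALSE),
      colocalizing = dplyr::coalesce(.data$colocalizing, FALSE),
      candidate = .data$is_ban & .data$near_lead & .data$colocalizing
    ) |>
    dplyr::arrange(dplyr::desc(.data$candidate),
                   dplyr::desc(dplyr::coalesce(.data$pph4, -1)),
                   .data$p_value)
  out
}
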