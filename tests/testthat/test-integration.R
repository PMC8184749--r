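test_that("proximity flags use inclusive distance from the whole gene interval", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chrom = "1",
    start = c(1e6, 1e6, 5e7),
    end = c(2e6, 2e6, 5.1e7)
  )
  # lead exactly 1 Mbp after gA's last base -> flagged; 1,000,001 -> not
  leads_in <- tibble::tibble(snp_id = "L1", chrom = "1",
                             pos = 2e6 - 1 + 1e6)
  leads_out <- tibble::tibble(snp_id = "L1", chrom = "1",
                              pos = 2e6 - 1 + 1e6 + 2)
  expect_true(genes_near_leads(genes, leads_in)[["gA"]])
  expect_false(genes_near_leads(genes, leads_out)[["gA"]])
  # overlap counts as distance 0
  expect_true(genes_near_leads(genes, tibble::tibble(
    snp_id = "L2", chrom = "1", pos = 1.5e6))[["gB"]])

  empty <- tibble::tibble(snp_id = character(0), chrom = character(0),
                          pos = numeric(0))
  expect_false(any(genes_near_leads(genes, empty)))

  bad <- tibble::tibble(snp_id = "L1", chrom = "chr1", pos = 1e6)
  expect_error(genes_near_leads(genes, bad), "mismatch")
})

test_that("enrichment odds ratio matches the cross-product and the exact-test oracle", {
  flat <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, 1)

  enr <- fisher_enrichment(10, 90, 5, 895)
  expect_equal(enr$odds_ratio, 10 * 895 / (90 * 5))
  expect_equal(round(enr$odds_ratio, 2), 19.89)
  expect_equal(enr$p, fisher_exact_oracle(10, 90, 5, 895), tolerance = 1e-10)

  # transpose invariance of the odds ratio
  expect_equal(fisher_enrichment(10, 5, 90, 895)$odds_ratio,
               enr$odds_ratio)

  # zero margin -> not estimable, p = 1
  zm <- fisher_enrichment(0, 0, 5, 95)
  expect_false(zm$estimable)
  expect_equal(zm$p, 1)

  # empty off-diagonal -> infinite OR, flagged
  inf <- fisher_enrichment(5, 0, 3, 10)
  expect_identical(inf$odds_ratio, Inf)
  expect_false(inf$estimable)

  expect_error(fisher_enrichment(-1, 2, 3, 4), "nonnegative")
})

test_that("interval overlap null matches a duplicate implementation and its edge cases", {
  sizes <- c(c1 = 1e6, c2 = 5e5)
  # loci tiling the genome: observed = all, percentile 100
  tiling <- tibble::tibble(chrom = c("c1", "c2"), start = c(0, 0),
                           end = c(1e6, 5e5))
  leads <- tibble::tibble(chrom = c("c1", "c2", "c2"),
                          pos = c(5e5, 1e5, 4e5))
  res <- interval_overlap_null(tiling, leads, sizes, n_perm = 50, seed = 1)
  expect_equal(res$observed, 2)
  expect_equal(res$percentile, 100)

  # no leads: observed 0, all null draws 0, percentile 100 by <= convention
  none <- tibble::tibble(chrom = character(0), pos = numeric(0))
  res0 <- interval_overlap_null(tiling, none, sizes, n_perm = 20, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$percentile, 100)

  # duplicate-implementation oracle with the same placement rule and stream
  loci <- tibble::tibble(chrom = c("c1", "c1", "c2"),
                         start = c(1e5, 7e5, 1e5), end = c(2e5, 8e5, 2e5))
  set.seed(33)
  leads2 <- tibble::tibble(chrom = sample(c("c1", "c2"), 20, replace = TRUE),
                           pos = floor(runif(20, 0, 4.9e5)))
  res2 <- interval_overlap_null(loci, leads2, sizes, n_perm = 200, seed = 9)

  lens <- loci$end - loci$start
  obs <- sum(vapply(seq_len(nrow(loci)), function(i) {
    any(leads2$chrom == loci$chrom[i] & leads2$pos >= loci$start[i] &
          leads2$pos < loci$end[i])
  }, logical(1)))
  set.seed(9)
  null <- vapply(seq_len(200), function(r) {
    cnt <- 0
    for (i in seq_along(lens)) {
      fits <- sizes[sizes >= lens[i]]
      ch <- sample(names(fits), 1, prob = fits - lens[i] + 1)
      st <- floor(runif(1, 0, sizes[[ch]] - lens[i] + 1))
      hit <- any(leads2$chrom == ch & leads2$pos >= st &
                   leads2$pos < st + lens[i])
      cnt <- cnt + hit
    }
    cnt
  }, numeric(1))
  expect_equal(res2$observed, obs)
  expect_equal(res2$null_counts, null)
  expect_equal(res2$percentile, 100 * mean(null <= obs))

  expect_error(
    interval_overlap_null(tibble::tibble(chrom = "c1", start = 0, end = 2e6),
                          leads, sizes), "longer")
})

test_that("candidate report requires BAN, proximity, and colocalization jointly", {
  ban <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    network = "combined", module = "M1",
    k = c(20, 18, 15, 12), overlap = c(10, 9, 2, 1),
    m = 20, n_bg = 180,
    p_value = c(1e-6, 1e-4, 0.2, 0.6),
    is_ban = c(TRUE, TRUE, FALSE, FALSE)
  )
  coloc <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    pph4 = c(0.9, 0.5, 0.95),
    colocalizing = c(TRUE, FALSE, TRUE),
    n_snps = 100
  )
  prox <- c(g1 = TRUE, g2 = TRUE, g3 = TRUE, g4 = FALSE)
  rep <- candidate_report(ban, coloc, prox)
  expect_identical(rep$gene[rep$candidate], "g1")
  # g2 is a proximal BAN whose pph4 = 0.5 -> excluded
  expect_false(rep$candidate[rep$gene == "g2"])
  # g3 colocalizes but is not a BAN -> excluded
  expect_false(rep$candidate[rep$gene == "g3"])
  # candidates sort first, then by pph4 and BAN p
  expect_identical(rep$gene[1], "g1")
  expect_true(all(c("k", "overlap", "p_value", "near_lead") %in% names(rep)))
})
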