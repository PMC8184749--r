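#' Colocalization priors
#'
#' Per-SNP prior probabilities that a SNP is associated with trait 1 only
#' (`p1`), trait 2 only (`p2`), or both (`p12`), plus the prior SD of true
#' effect sizes used by the approximate Bayes factor. Defaults are the
#' quantitative-trait convention.
#'
#' @param p1,p2,p12 Per-SNP priors; must be positive with
#'   `p1 + p2 + p12 < 1`.
#' @param prior_effect_sd Prior SD of the true effect (W = sd^2).
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_effect_sd = 0.15) {
  if (any(c(p1, p2, p12) <= 0)) abort("priors must be positive")
  if (p1 + p2 + p12 >= 1) abort("p1 + p2 + p12 must be < 1")
  if (prior_effect_sd <= 0) abort("`prior_effect_sd` must be > 0")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_effect_sd = prior_effect_sd), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_effect_sd^2`, `r = W/(V + W)` and
#' `z = beta/se`, returns `0.5 * (log(1 - r) + r * z^2)`: the log Bayes
#' factor for association versus the null at one SNP. Vectorized over
#' `beta` and `se`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), positive.
#' @param prior_effect_sd Prior SD of the true effect.
#' @return Log ABF value(s).
#' @export
log_abf <- function(beta, se, prior_effect_sd = 0.15) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0)) {
    abort("`beta` and `se` must be finite with se > 0")
  }
  V <- se^2
  W <- prior_effect_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Five-hypothesis colocalization posteriors
#'
#' Combines per-SNP log Bayes factors for two traits over the same aligned
#' SNP panel into posterior probabilities of the five hypotheses: H0 no
#' association, H1/H2 association with one trait only, H3 both traits with
#' two distinct causal SNPs, H4 both traits sharing one causal SNP. Uses
#' log-sum-exp stabilized sums `S1, S2, S12` and the unnormalized weights
#' `1, p1*S1, p2*S2, p1*p2*(S1*S2 - S12), p12*S12`.
#'
#' @param labf1,labf2 Equal-length per-SNP log ABF vectors, SNP-aligned.
#' @param priors A [coloc_priors()].
#' @param pph4_threshold Posterior threshold for the colocalization call.
#' @return List of class `coloc_result`: `pph0..pph4`, `n_snps`,
#'   `colocalizing`.
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors(),
                             pph4_threshold = 0.75) {
  if (length(labf1) != length(labf2) || !length(labf1)) {
    abort("`labf1` and `labf2` must be aligned, equal-length, nonempty")
  }
  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lS12 <- logsumexp(labf1 + labf2)
  l0 <- 0
  l1 <- log(priors$p1) + lS1
  l2 <- log(priors$p2) + lS2
  # S1*S2 - S12 >= 0 up to rounding; clamp the log-difference at -Inf
  diff_arg <- lS12 - lS1 - lS2
  l3 <- if (diff_arg >= 0) -Inf else {
    log(priors$p1) + log(priors$p2) + lS1 + lS2 + log1p(-exp(diff_arg))
  }
  l4 <- log(priors$p12) + lS12
  lall <- c(l0, l1, l2, l3, l4)
  pp <- exp(lall - logsumexp(lall))
  pp <- pp / sum(pp)
  structure(list(pph0 = pp[1], pph1 = pp[2], pph2 = pp[3], pph3 = pp[4],
                 pph4 = pp[5], n_snps = length(labf1),
                 colocalizing = pp[5] >= pph4_threshold),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d SNPs  PPH0-4: %.3f %.3f %.3f %.3f %.3f  %s\n",
    x$n_snps, x$pph0, x$pph1, x$pph2, x$pph3, x$pph4,
    if (x$colocalizing) "colocalizing" else "not colocalizing"))
  invisible(x)
}

check_assoc_stats <- function(stats, what) {
  need <- c("snp", "chr", "bp", "beta", "se", "maf", "n")
  if (!all(need %in% names(stats))) {
    abort(paste0(what, " must have columns ", paste(need, collapse = ", ")))
  }
  if (any(stats$se <= 0)) abort(paste0(what, ": all se must be > 0"))
  if (anyDuplicated(stats$snp)) abort(paste0(what, ": duplicate snp ids"))
  stats
}

#' Colocalization scan around a GWAS lead SNP
#'
#' Restricts both summary-statistic sets to the window around the lead
#' position (inclusive boundary), intersects them on SNP id, computes
#' per-SNP log ABFs for each trait, and evaluates the five-hypothesis
#' posterior with the PPH4 >= `pph4_threshold` colocalization call.
#'
#' @param gwas,eqtl Summary-statistic tibbles with columns
#'   `snp, chr, bp, beta, se, maf, n`.
#' @param lead_position Lead SNP base-pair position.
#' @param window Half-window in bp (SNPs with
#'   `|bp - lead_position| <= window` are kept).
#' @param priors A [coloc_priors()].
#' @param pph4_threshold Posterior threshold for the call.
#' @return A `coloc_result` (see [coloc_posteriors()]).
#' @export
run_coloc_scan <- function(gwas, eqtl, lead_position, window = 200000,
                           priors = coloc_priors(), pph4_threshold = 0.75) {
  gwas <- check_assoc_stats(gwas, "gwas")
  eqtl <- check_assoc_stats(eqtl, "eqtl")
  g <- gwas[abs(gwas$bp - lead_position) <= window, ]
  e <- eqtl[abs(eqtl$bp - lead_position) <= window, ]
  if (!nrow(g) || !nrow(e)) {
    abort("no SNPs inside the window around the lead (no positional overlap)")
  }
  shared <- intersect(g$snp, e$snp)
  if (!length(shared)) {
    abort("window SNP sets do not intersect on snp id (no shared panel)")
  }
  g <- g[match(shared, g$snp), ]
  e <- e[match(shared, e$snp), ]
  res <- coloc_posteriors(
    log_abf(g$beta, g$se, priors$prior_effect_sd),
    log_abf(e$beta, e$se, priors$prior_effect_sd),
    priors = priors, pph4_threshold = pph4_threshold
  )
  res
}
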