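---
title: "netban: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netban: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netban)
```

`netban` nominates causal genes at bone-density GWAS loci by combining
four statistical machines: weighted co-expression modules, per-module
Bayesian networks, hypergeometric key-driver ("bone-associated node",
BAN) statistics, and GWAS–eQTL colocalization. This vignette explains
each model, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions the implementation commits to.

## 1. Preprocessing

Two filters act on raw counts. The expression filter keeps genes with
**more than** 6 reads *and* more than 0.1 TPM (jointly, per sample) in
more than 20% of samples; all inequalities are strict. The network
filter then removes genes with fewer than 10 reads in more than 90% of
samples, and genes not on an autosome or the X chromosome.

Normalization is `log2(CPM + 1)` followed by per-gene linear-model
residualization: a design over `adjust_for` ∪ `protect` covariates is
fitted and only the fitted `adjust_for` components (typically batch) are
subtracted, so protected biology (sex, age) survives. Two deliberate
simplifications relative to common practice: the variance-stabilizing
transform is replaced by the closed-form `log2(CPM + 1)` (a monotone
transform is adequate for a correlation-based network), and
empirical-Bayes batch correction is replaced by plain residualization
with protected covariates — deterministic, dependency-free, and with
the same first-order effect. Re-adjusting already-adjusted data changes
nothing (the batch coefficients refit to ~0), which the tests check.

## 2. Co-expression modules

The signed adjacency is $a_{ij} = ((1 + \mathrm{cor}(x_i,x_j))/2)^\beta$
with Pearson correlation; $\beta = 4$ by default (5 is the conventional
preset for male-only networks). Anti-correlated pairs get $a \to 0$,
so "signed" modules never mix opposing profiles. The topological
overlap is

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i,k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},\;
  k_i = \sum_{u \ne i} a_{iu},$$

and modules are found by average-linkage clustering of $1-\mathrm{TOM}$
with a **static cut**, a minimum module size of 30, and iterative
eigengene merging at dissimilarity $1 - \mathrm{cor} < 0.15$ (closest
pair first, eigengenes recomputed after every merge; the module count
strictly decreases so merging terminates). Labels are `M1, M2, ...` by
decreasing size; genes in dropped clusters are `"unassigned"`.

**Default cut height.** A fixed fraction of the maximum merge height is
a poor default for TOM trees: uncorrelated genes do not sit at
dissimilarity 1 but at a noise plateau (~0.9–0.97 here), so a cut at
0.99 × max height swallows the noise merges and absorbs background
genes into modules. The default is therefore the midpoint of the
largest gap among the upper half of the merge heights — tight clusters
merge low, noise merges high, and the widest gap between them is where
a static cut belongs. It is deterministic, has no tuned constant, and
`cut_height` remains user-settable for trees without a clean gap.

The module eigengene is the first principal component of the
gene-standardized module submatrix, unit-norm over samples,
sign-aligned with the module's mean expression profile; for the
degenerate two-gene anti-correlated module the tie is broken toward the
first gene in id order. Eigengene–trait association uses Spearman's
rho with asymptotic two-sided p-values, pairwise-complete observations,
and no multiplicity adjustment (the table is reported as nominal
screening evidence); pairs with fewer than 4 complete observations are
flagged not estimable.

## 3. Per-module Bayesian networks (MMHC)

Structure learning is Max-Min Hill Climbing: a constraint-based
skeleton, then score-based orientation.

*Skeleton (MMPC).* Conditional independence is tested with the
Fisher-z statistic $z = \mathrm{atanh}(r)\sqrt{n - |S| - 3}$, where the
partial correlation $r$ comes from inverting the ridge-stabilized
correlation submatrix over $\{i,j\} \cup S$. Per target, candidates are
added by the max-min heuristic (admit the variable whose weakest
association over subsets of the current set is strongest), variables
found independent given any subset are removed permanently, and a
backward sweep removes members independent given a subset of the rest.
The final skeleton keeps a pair only if each gene is in the other's
set (AND symmetrization).

*Orientation.* Greedy hill climbing from the empty graph over
add/delete/reverse moves, additions restricted to skeleton pairs, all
states acyclic, scored by the decomposable Gaussian BIC
$\sum_v \big[\hat\ell_v - \tfrac{|pa_v| + 2}{2}\log n\big]$
(per-node parameters: coefficients, intercept, residual variance).
One best improving move per iteration; ties break lexicographically by
(operator, source, target), which fixes the orientation of
score-equivalent structures and makes runs reproducible bit for bit.

Defaults: $\alpha = 0.05$, conditioning sets up to size 3, ridge
$10^{-8}$, iteration cap 500 (exceeding it returns the current DAG with
a warning flag), and modules larger than 1,000 genes are refused
outright rather than silently subsampled. These are conventional
hybrid-learner settings; the study this design follows printed only the
algorithm name, so all are exposed in `bn_config()`.

## 4. BAN statistics

Within each network set the module DAGs are pooled, each gene's 3-step
**undirected** neighborhood size (including itself) is computed, and
candidates are pruned in two stages: neighborhood size ≤ 2, then size
below (mean − sample SD) of the remaining sizes. Pruning statistics are
computed per network set; pruning can never remove a gene at or above
the pooled mean. For each retained gene the BAN p-value is the
upper-tail hypergeometric probability of drawing at least `overlap`
bone genes in `k` draws from a universe of `m` bone and
`universe − m` non-bone genes, with the universe fixed at the
**pre-pruning** network gene count. The BAN call is nominal
`p ≤ 0.05`, deliberately unadjusted — BAN status is a screening
annotation that downstream colocalization must corroborate, not a
stand-alone discovery claim. Neighborhoods ignore edge direction: a
gene regulating, and one co-regulated with, bone genes are both
interesting, and 3 steps in a DAG read causally in either direction.
The bone-vs-non-bone connectivity comparison is a one-sided Wilcoxon
rank-sum test (normal approximation with tie correction; an all-tied
table returns p = 1).

## 5. Colocalization

Per SNP, the Wakefield log approximate Bayes factor is
$\tfrac12(\log(1-r) + r z^2)$ with $V = se^2$, $W$ the squared prior
effect SD, $r = W/(V+W)$, $z = \beta/se$. With per-SNP sums
$S_1, S_2, S_{12}$ (log-sum-exp stabilized), the five hypothesis
weights are $1,\; p_1 S_1,\; p_2 S_2,\; p_1 p_2 (S_1 S_2 - S_{12}),\;
p_{12} S_{12}$, normalized to posteriors PPH0–PPH4. The H3 term is
clamped at zero if rounding drives it negative; with one SNP it is
exactly zero. Priors default to the quantitative-trait convention
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, prior effect SD 0.15; all
are configurable. The scan takes both traits' statistics within
±200 kb of the lead SNP (inclusive boundary), intersects on SNP id,
and calls colocalization at PPH4 ≥ 0.75. The model assumes a single
causal variant per trait in the window; an empty window and an empty
SNP-id intersection raise distinct errors. PPH4/PPH3 ratios can be
computed from the output but are not used for calling.

## 6. Integration

Gene-to-lead proximity uses the whole gene interval (0-based,
half-open; minimum distance, inclusive ≤ 1 Mbp; a TSS mode would be a
one-line change and the paperwork default is the interval). Enrichment
tables report the cross-product odds ratio $(ad)/(bc)$ with the
two-sided Fisher exact p; a zero margin is reported as not estimable
with p = 1, and an empty off-diagonal as an infinite-OR sentinel. The
locus-overlap null places length-matched intervals uniformly at random
(chromosome chosen proportional to placeable length), allows overlaps
among null intervals, and reports the ≤-convention percentile of the
observed count, matching how a discrete permutation null is usually
quoted. Candidates are genes that are BAN ∧ GWAS-proximal ∧
colocalizing, sorted by PPH4 then BAN p, with all intermediate columns
retained for audit.

## 7. The synthetic-data generator

`gen_expression_study()` emulates the *structure* the pipeline
consumes, not any particular tissue. Per module, an eigengene vector is
standard normal over samples; gene $g$ has latent signal
$\lambda e_m + \sqrt{1-\lambda^2}\, u_g$ with loading $\lambda$ from
`loading_range` (reference: fixed 0.8, so mean within-module latent
correlation ≈ $\lambda^2$ = 0.64, slightly above when the structured
residual is counted). The residuals $u$ are a standardized
linear-Gaussian SEM sample from the module's planted DAG — a
breadth-first tree whose root (the *driver*) branches to 4 hubs, deeper
nodes to 2, edge weights uniform on [0.4, 0.75]. Moderate weights keep
the shared factor dominant for module detection while leaving enough
partial-correlation signal for structure learning; the hub root mirrors
how key drivers look in real networks and keeps the driver's
neighborhood large enough to survive pruning. Bone-gene labels go to a
configured subset of modules (default: the first half, rounded down —
in real studies only a minority of modules represent bone processes)
at the tree positions deepest-but-within-3-steps of the driver, so the
driver's neighborhood is uniquely enriched: other hubs reach only their
own subtree's share. Counts are negative binomial with mean
`exp(baseline + latent + batch shift)` and shared dispersion (default
0.1); batches are contiguous sample blocks with per-gene shifts of SD
0.3 on the log scale — enough to visibly distort a network if left
uncorrected, removable by design. Sample size defaults to 200, five
modules of 40 genes plus 100 background genes: large enough for stable
module recovery and 3-step neighborhoods, small enough that the whole
pipeline runs in seconds.

`gen_assoc_pair()` simulates two independent cohorts (no sample
overlap, matching the GWAS-consortium vs eQTL-panel setting) of
haplotype pairs over one SNP panel. MAFs are marginally
Uniform(0.05, 0.5) but drawn through a Gaussian copula whose
correlation exceeds the LD target, because two binary alleles can only
correlate strongly if their frequencies are close (the Fréchet bound);
with near-equal neighboring MAFs, the allele-level Markov chain is
calibrated so adjacent dosage correlation hits `ld_rho` (clamped to the
feasible range — measured mean ≈ 0.895 at a target of 0.9). Causal
SNPs explain `var_explained` (default 1%) of trait variance; H4 plants
one shared SNP mid-panel, H3 two well-separated SNPs (25%/75%
positions), H1/H2 one trait only. Reported statistics are genuine
marginal OLS `beta`/`se` from the simulated genotypes, not injected
z-scores. What this generator does **not** emulate: realistic human LD
maps and recombination hotspots, allele-frequency/effect-size coupling,
imputation uncertainty, annotation-aware gene placement, or
between-tissue eQTL sharing. Passing tests therefore demonstrate the
statistical machinery is correct and well calibrated under its own
assumptions, not that any particular real-data claim reproduces.

## 8. Pipeline, determinism, and problem sizes

`run_pipeline()` executes simulate → preprocess → modules → networks →
BAN → coloc → integrate from a single `pipeline_config()`, whose
defaults carry every printed threshold (power 4, min module size 30,
merge height 0.15, step size 3, BAN p ≤ 0.05, ±200 kb window, 1 Mbp
proximity, PPH4 ≥ 0.75). Every random draw flows through stage-scoped
sub-seeds derived from the one global seed, so identical config + seed
gives byte-identical artifacts and report; stages are cheap at package
scale and are simply re-executed (no caching layer). In the simulated
study, one GWAS lead SNP is placed at each planted driver's midpoint
plus decoy leads at random background genes; colocalization is run only
for GWAS-proximal BANs (as the original design does), with H4
architecture at planted causal genes and H1 (GWAS-only) elsewhere.
Unknown config keys are rejected by name, top-level and per block.

Test and acceptance problem sizes were chosen as the smallest designs
where each property is comfortably identifiable — e.g. n = 5,000 and 1%
variance explained give causal |z| ≈ 7, n = 200 with loading 0.8 gives
ARI = 1 module recovery, 10-node DAGs at n = 4,000 give near-exact
skeletons — and the suite checks properties (recovery rates, medians
over seeds, oracle equalities) rather than single stochastic draws.

## 9. Known limitations

- The static-cut + merge module detector is simpler than dynamic
  hybrid tree cutting; on real data with nested module structure it
  will be more conservative, and `cut_height` may need manual choice.
- MMPC with Fisher-z assumes approximately Gaussian expression after
  normalization; heavy-tailed genes can inflate the skeleton.
- Single-causal-variant colocalization: allelic series at one locus
  push posterior mass toward H3. No allele harmonization is attempted —
  inputs are assumed on a shared strand and effect allele.
- The BAN universe convention (pre-pruning count) follows the source
  design; with very aggressive pruning the test is slightly
  conservative.
- Hill climbing is plain greedy (no tabu/restarts): it can stop in a
  local optimum on dense modules, though the skeleton restriction makes
  this rare at module scale.
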