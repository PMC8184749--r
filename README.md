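# netban

Network-based nomination of causal genes at bone-mineral-density (BMD)
GWAS loci.

GWAS find thousands of loci for bone density, but each locus only points
at a neighborhood of the genome, not at a gene. `netban` implements a
systems-genetics strategy for closing that gap, aimed at researchers who
have bulk RNA-seq from a disease-relevant tissue plus public GWAS/eQTL
summary statistics:

1. **Co-expression modules.** From filtered, batch-adjusted expression,
   build a signed weighted network, `a_ij = ((1 + cor(x_i, x_j))/2)^beta`
   (default `beta = 4`), convert it to the topological overlap matrix
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, and cluster
   `1 - TOM` by average linkage. Modules smaller than 30 genes are
   dropped and modules whose eigengenes (first principal components)
   have dissimilarity `1 - cor < 0.15` are merged.
2. **Per-module Bayesian networks.** Learn a directed acyclic network for
   each module by Max-Min Hill Climbing: an MMPC constraint phase
   (Fisher-z partial-correlation tests, AND-symmetrized) proposes a
   skeleton, and greedy hill climbing over add/delete/reverse moves,
   restricted to the skeleton and scored by the Gaussian BIC, orients it.
3. **Bone-associated nodes (BANs).** For every gene, count the genes in
   its 3-step (undirected) network neighborhood, including itself. After
   pruning weakly connected genes (neighborhood size <= 2, then size <
   mean - SD), test whether the neighborhood is enriched for *known bone
   genes* with the upper-tail hypergeometric probability
   `P(X >= overlap)` (the `q = overlap - 1, lower.tail = FALSE`
   convention), with the universe fixed at the pre-pruning network gene
   count. Genes at nominal `p <= 0.05` are BANs.
4. **GWAS–eQTL colocalization.** For BANs within 1 Mbp of a GWAS lead
   SNP, take both traits' summary statistics within ±200 kb of the lead,
   compute per-SNP Wakefield log approximate Bayes factors
   `0.5 (log(1 - r) + r z^2)` with `r = W/(V + W)`, and evaluate the
   five-hypothesis posterior (H0 none, H1/H2 one trait, H3 two causal
   SNPs, H4 one shared SNP). A gene colocalizes when `PPH4 >= 0.75`.
5. **Integration.** Candidate causal genes are BANs that are both
   GWAS-proximal and colocalizing; the package also computes enrichment
   odds ratios (cross-product OR + Fisher exact p) and a permutation
   null for locus/lead-SNP overlap (length-matched random intervals).

Because the original study's inputs (192-mouse cortical-bone RNA-seq,
GTEx, human BMD GWAS) are far beyond desk scale, the package ships a
first-class synthetic-data module that generates every input with
planted ground truth: modular negative-binomial counts over a latent
factor + structural-equation model, linear-Gaussian SEM samples from
known DAGs, and paired GWAS/eQTL summary statistics with AR(1) linkage
disequilibrium under any of the five colocalization hypotheses. Every
stage of the pipeline is therefore testable end to end.

## Worked example

The whole pipeline runs from one seeded configuration:

```r
library(netban)

run <- run_pipeline(pipeline_config(seed = 42))
run
#> <netban_run> seed 42
#>   genes: 300 simulated, 300 expressed, 300 in network
#>   modules: 5 (ARI vs truth 1.000)
#>   BAN: 166 tested, 64 called, 8 near a lead
#>   coloc: 2 colocalizing; candidates: 2 (precision 1.00, recall 1.00)
```

The reference synthetic study has 200 samples, five planted 40-gene
modules (factor loading 0.8) and 100 background genes; two modules carry
known-bone-gene labels and their hub (driver) genes are the planted
causal genes. The report above says: all five modules were recovered
exactly (adjusted Rand index 1.0 against the planted partition), 64
genes showed nominal BAN evidence, and after requiring GWAS proximity
and a colocalizing eQTL the candidate list contains exactly the two
planted drivers — nothing else.

Results are tibbles, with broom-style accessors for fitted objects:

```r
glance(run$partition)
#> # A tibble: 1 × 5
#>   network  n_modules n_genes n_unassigned largest_module
#> 1 combined         5     300          100             40

glance(run$networks$combined$M1)
#> # A tibble: 1 × 3
#>   n_nodes n_edges   score
#> 1      40      76 -12085.

dplyr::filter(run$candidates, candidate) |>
  dplyr::select(gene, module, k, overlap, p_value, pph4)
#> # A tibble: 2 × 6
#>   gene     module     k overlap p_value  pph4
#> 1 gene0041 M2        30       9 0.00320 0.999
#> 2 gene0001 M1        32       9 0.00534 0.989
```

Here `k` is the gene's 3-step network neighborhood size, `overlap` the
known bone genes inside it, `p_value` the hypergeometric BAN p-value,
and `pph4` the posterior probability that the gene's eQTL shares a
causal variant with the GWAS signal. `autoplot()` methods exist for
partitions and colocalization results, and `plot_ban_overview()` shows
the BAN landscape.

Each stage is equally usable on its own (`filter_expressed()`,
`normalize_adjust()`, `signed_adjacency()` → `tom_similarity()` →
`detect_modules()`, `mmpc_skeleton()` → `hill_climb()`, `run_ban()`,
`run_coloc_scan()`, `candidate_report()`), reading and writing plain
TSV/BED via the `read_*`/`write_*` helpers.

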