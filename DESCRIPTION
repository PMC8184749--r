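Package: netban
Title: Network-Based Nomination of Causal Genes at Bone-Density GWAS Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Co-expression network analysis for nominating causal genes at
    GWAS loci. Builds signed weighted co-expression networks and detects
    modules via topological overlap, learns a Gaussian Bayesian network per
    module with the Max-Min Hill Climbing algorithm, scores genes as
    bone-associated nodes (BANs) by hypergeometric enrichment of known bone
    genes in their 3-step network neighborhoods, colocalizes GWAS and eQTL
    summary statistics with Wakefield approximate Bayes factors under the
    five-hypothesis posterior, and integrates the evidence into a ranked
    candidate-gene report with enrichment odds ratios and a permutation
    null for genomic interval overlap. A synthetic-data module generates
    modular RNA-seq counts, linear-Gaussian structural-equation data from
    known DAGs, and paired GWAS/eQTL summary statistics with AR(1) linkage
    disequilibrium, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
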