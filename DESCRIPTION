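Package: pleioscan
Title: Cross-Phenotype GWAS Sharing, Enrichment and Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects shared genetic architecture between pairs of traits from
    GWAS summary statistics. Builds ancestry-specific linkage-disequilibrium
    (LD) proxy tables from phased haplotype panels, reduces each trait to
    independent lead SNPs by greedy LD clumping, identifies loci shared
    between trait pairs directly or through LD proxies, merges shared SNPs
    into independent blocks, scores every pair with a hypergeometric
    enrichment test (computed in log space so p-values far below double
    underflow remain representable) together with Jaccard, Sorensen and
    Chao-Sorensen similarity indices, and applies Benjamini-Hochberg and
    Bonferroni multiple-testing correction. Shared regions can be followed up
    with approximate-Bayes-factor colocalization (posterior probabilities
    PP0-PP4 and per-SNP causal contributions). A fully seeded synthetic-data
    generator produces haplotype panels with controlled LD-block structure
    and trait pairs with planted shared loci so the whole pipeline is
    testable without external downloads.
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
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
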