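Package: pathARTP
Title: Pathway-Based Case-Control GWAS Analysis with the Adaptive Rank
    Truncated Product Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pathway-based analysis of case-control genotype
    data: genotype input (binary PLINK and a plain-text dialect), SNP- and
    sample-level quality control with an exact Hardy-Weinberg test,
    SNP-to-gene assignment through asymmetric flanking windows, principal
    components of standardized genotypes for stratification adjustment,
    covariate-adjusted additive logistic association with a fast Rao score
    test for permutation use, linkage-disequilibrium signal grouping, and
    permutation-based adaptive rank truncated product (ARTP) inference at
    the gene and pathway level from a shared permutation ensemble. A
    synthetic cohort generator with block-LD genotypes, planted per-allele
    odds ratios and optional population stratification supports testing
    every stage without access to controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
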