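Package: cnvherit
Title: Partitioning Additive Genetic Variance Between SNP and CNV Genomic
    Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relative contribution of copy number
    variants (CNVs) and single nucleotide polymorphisms (SNPs) to the
    additive genetic variance of quantitative traits, using deregressed
    estimated breeding values as pseudo-phenotypes. Implements genotype
    quality control (call-rate, autosome, Mendelian-inconsistency and
    effective-record-contribution filters), dual-caller CNV consensus
    merging with a one-SNP endpoint tolerance, VanRaden method 1 genomic
    relationship matrices with two CNV recoding procedures, weighted
    average-information REML for single- and two-GRM mixed models with a
    boundary log-likelihood ratio test and a two-step residual procedure,
    joint SNP+CNV relaxed-LASSO association with principal-component
    stratification covariates, per-variant variance explained, single-marker
    mixed-model t-tests, and QTL window designation and merging. A
    synthetic-population generator with a known SNP/CNV variance split
    provides ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    jsonlite,
    generics,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr
Config/testthat/edition: 3
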