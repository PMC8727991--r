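Package: mamutspec
Title: Mutation Rate and Spectrum Analysis for Mutation Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome mutation accumulation (MA)
    experiments, motivated by mismatch-repair-impaired Caenorhabditis elegans
    lines. Provides cross-line binomial verification of candidate variant
    calls with Holm-Bonferroni retention, microsatellite and homopolymer
    repeat cataloguing with triplet sequence-complexity statistics,
    partitioned per-line mutation-rate and spectrum estimation (including
    strand-collapsed substitution classes, trinucleotide context, indel size
    accounting and heteroplasmy-weighted mitochondrial rates), and a
    penalized logistic regression model of site mutability with odds-ratio
    reporting and bin-wise rate calibration. A synthetic-data module
    simulates complete MA experiments (genome, annotation layers, planted
    mutations, read support) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    stringi,
    readr,
    jsonlite,
    vcfR,
    ggplot2,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
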