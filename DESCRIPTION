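Package: alureg
Title: Transposable Element Expression, Methylation and Regulatory
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for linking transposable element
    (TE) expression to gene regulation, DNA methylation and phenotype in
    case/control brain transcriptome studies. Classifies TE loci against
    gene models into exon, intron and upstream-distance classes; runs
    cis- and trans-regulation Pearson correlation screens with per-group
    Benjamini-Hochberg control and overlap-set algebra; profiles
    differentially expressed TE family composition; builds
    reference-anchored consensus and conservation profiles for repeat
    sequence sets and scans them with JASPAR-format position weight
    matrices using relative scores; quantifies global and locus-specific
    DNA methylation from COBRA gel band intensities; computes 2^-ddCt
    fold changes; and correlates molecular measures with clinical scores.
    A fully seeded synthetic-data generator with machine-readable ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
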