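Package: trfscan
Title: Discovery and Integrative Analysis of tRNA-Derived Small RNA Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering tRNA-derived fragments (tRFs) in small-RNA
    sequencing data and tracing their downstream regulatory footprint. The
    package detects anomalous read-length peaks between sample groups,
    decomposes a peak into its constituent sequences, places candidate
    fragments on a genome and classifies them against tRNA gene annotation
    (tRF-5/tRF-3/tRF-1/halves), quantifies and tests group differences
    (including 2^-ddCt relative quantification of qPCR data), predicts
    targets with a seed-weighted complementarity aligner, intersects
    predicted targets with down-regulated proteins under a hypergeometric
    model, and screens metabolites with a Pareto-scaled PLS-DA VIP
    procedure. A synthetic-data generator reproduces the statistical
    structure of a coarse-vs-fine wool lamb skin study so that every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
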