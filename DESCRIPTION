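Package: polytereg
Title: Subgenome Regulatory Divergence and Transposable-Element Exaptation
    in Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for transcription-factor cistromes in polyploid
    genomes with diverged subgenomes. Classifies genomic regions by subgenome
    homology from reciprocal whole-genome alignment blocks, calls
    high-occupancy target (HOT) regions from merged binding sites, scores
    promoter TF affinity (TFAS) with distance-decayed peak densities,
    classifies homoeologous gene triads into balanced and unbalanced binding
    patterns, computes transposable-element (TE) subfamily enrichment,
    detects degenerated TE relics in sister promoters with a permutation
    control, and profiles TE expansion epochs and LTR insertion ages with
    Kimura two-parameter distances. Includes a seeded synthetic three-subgenome
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
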