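Package: tncomp
Title: Competitiveness Analysis of Transposon Insertion Sequencing Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A complete pipeline for Tn-seq competitiveness screens built on
    mariner/HIMAR1 insertion libraries sequenced via MmeI junction tags: fuzzy
    detection and trimming of the transposon end sequence in raw FASTQ reads,
    exact and unique mapping of the short genomic tag adjacent to each
    junction, per-site tallies with IGV-compatible tracks, gene-level
    aggregation with edge exclusion, intergenic-read normalization across
    samples, and per-gene competition indices (treated/untreated) classified
    by two-replicate fold-change concordance. Includes a transposon-library
    selection simulator with known ground truth so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringi,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
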