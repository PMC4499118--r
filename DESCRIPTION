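Package: splicestage
Title: Splicing-Stage Classification and Splicing-Order Analysis for Nuclear RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of paired-end RNA-seq from nuclear or
    pre-mRNA-enriched libraries, where reads sample transcripts at mixed
    stages of splicing. Classifies read pairs into pre-, intermediate- and
    post-splicing categories from end labels and mapping distance; computes
    a per-splice-site Splice Site Index (SSI) from junction- and
    boundary-spanning reads together with median exon/intron coverage;
    detects non-sequential removal of adjacent introns from coverage
    differences (first-quartile rule) and a read-based splice-ratio with
    multi-sample consistency and a DNA-control filter; and detects
    recursive (multi-step) intron splicing from the signed derivative of
    inverted split-gap coverage, with cross-sample consensus peaks, a
    donor-by-acceptor junction matrix, splice-motif canonicality and
    novel-exon flagging. Includes a deterministic paired-end read simulator
    for loci sampled at configurable splicing stages, used as the fixture
    generator for all tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
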