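Package: glycofam
Title: Gene-Family Identification, Intron Architecture, and
    Expression-Metabolite Linking for Plant Glycosyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of plant gene families defined by
    a conserved protein motif, modelled on the UDP-glycosyltransferase (UGT)
    family and its diagnostic C-terminal PSPG box. Identifies family members
    by Smith-Waterman local alignment of a 44-residue consensus motif, builds
    neighbor-joining trees from protein alignments and assigns phylogenetic
    groups via labelled anchor sequences, extracts introns from gene models
    and classifies their phases, projects intron positions onto a protein
    multiple alignment to detect conserved intron-insertion events, summarises
    tissue-level and stress-response expression patterns, and ranks candidate
    genes by transcript-metabolite correlation. A seeded synthetic-family
    generator emits a genome, gene models, proteins, a true alignment,
    expression and metabolite matrices with machine-readable planted truth, so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
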