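Package: tssarna
Title: Detection and Analysis of Transcription Start Site-Associated Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription start site-associated small RNAs (TSSaRNAs)
    from strand-specific small-RNA read alignments by locating the most
    frequent read 5' start near each annotated start codon and splitting the
    read population at that coordinate into one full-length small-RNA species
    and truncated cognate-gene reads. Classifies calls as primary transcripts
    from paired TEX-treated/untreated dRNA-seq libraries, scores differential
    expression of TSSaRNAs against their cognate genes on tiling-array
    intensity series over a growth curve, and simulates the RNA polymerase
    pausing model of TSSaRNA biogenesis (deterministic polymerase traffic with
    an initiation interval, site-specific stall times, and collision-triggered
    early termination). A synthetic-data generator produces toy genomes,
    planted read populations, TEX pairs and probe matrices with
    machine-readable truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
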