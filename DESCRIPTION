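Package: prnascreen
Title: Structure-Based Discovery of Phage Packaging RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies phi29-like packaging RNAs (pRNAs) in viral genomes
    by conserved secondary structure rather than primary sequence.
    Provides pseudoknot-free base-pair-maximization folding with
    three-way-junction detection, a string search for complementary
    left-hand/right-hand kissing loops with experimentally derived
    activity rules, a directed pairing-graph model of hand-in-hand
    hexameric ring closure, alignment conservation statistics
    (existence and sequence-similarity rates per annotated feature
    region), Smith-Waterman motor-protein co-occurrence checks,
    neighbor-joining patristic-distance reports, and a synthetic-data
    generator producing structure-conserved, sequence-divergent pRNA
    families with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
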