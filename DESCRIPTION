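Package: igjunction
Title: Junctional Diversity Analysis of Immunoglobulin V(D)J Recombinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation and summarization of immunoglobulin V(D)J junctions
    in cDNA repertoires, developed around the bovine fetal preimmune
    repertoire. Assigns germline V, D and J segments by parameterized
    Smith-Waterman local alignment, decomposes VD/DJ/VJ junctions into
    exonuclease-trimmed, palindromic (P) and nontemplated (N) nucleotides,
    tabulates gene-segment usage and junction statistics, computes CDR3
    spectratypes, mines genomic contigs for diversity segments flanked by
    recombination signal sequences with a fuzzy PROSITE-style scanner, and
    deduces uncatalogued D segments by consensus across recombinations.
    Includes a ground-truth-labelled repertoire simulator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
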