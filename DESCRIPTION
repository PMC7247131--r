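Package: rleaderScreen
Title: Screening Candidate Ribosomal Leader RNAs from Comparative Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen structure-annotated RNA alignments for candidate
    ribosomal leaders (r-leaders), the cis-regulatory RNA elements in the
    5' UTRs of ribosomal protein operons. Reads and writes Stockholm-format
    alignments with consensus secondary structure, classifies base-pair
    columns and evaluates covariation support (a permissive two-variant rule
    and a permutation-based G-test of column association with
    Benjamini-Hochberg correction), infers putatively regulated operons from
    gene context using intergenic-distance and cross-occurrence consistency
    heuristics, predicts the r-protein ligand of each motif with a two-pass
    Only/Prior/Closest decision procedure, checks placement against
    transcription start sites, and filters candidates overlapping previously
    published RNAs. Includes generators for synthetic alignments evolved on a
    phylogeny with compensatory mutations and for synthetic genome layouts, so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
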