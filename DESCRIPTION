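Package: tirmap
Title: Assembly-Based Discovery and Mapping of DNA Transposon Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers, maps and classifies class-II (DNA) transposon
    insertions in assembled genomes using terminal-inverted-repeat (TIR)
    anchored junction queries. Extracts genome-transposon junction sequences
    from assembly contigs, maps them onto a reference genome, classifies
    insertions as reference-conserved or sample-specific, detects target
    site duplications, reconstructs internally deleted element variants
    (KP-style) by multiple alignment and plurality consensus, computes
    Kimura two-parameter divergence landscapes, and summarises insertion
    density across gene and heterochromatin annotations. Includes a
    synthetic genome simulator with machine-readable truth tables for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
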