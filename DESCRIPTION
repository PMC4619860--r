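Package: pirnakit
Title: Analysis of piRNA Populations from Small RNA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising PIWI-interacting RNA (piRNA)
    populations from aligned small RNA sequencing libraries: piRNA calling
    by length and 1U/10A sequence features, exclusive hierarchical genomic
    annotation, detection of non-templated 3' adenylation and uridylation,
    binned genome-wide expression profiles stratified by read length with
    interval denesting and unique 5' end counting, quantification of 5'
    versus 3' truncation between short and long alignment pools, and
    opposite-strand 5'-overlap (ping-pong) signature statistics. Includes a
    synthetic read simulator with full ground truth so every stage can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
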