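Package: pairtcr
Title: Paired Single-Cell TCR Alpha/Beta Amplicon Analysis and Expression Cloning In Silico
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for well-based paired T-cell receptor (TCR) alpha/beta
    repertoire sequencing. Simulates matrix-barcoded 384-well amplicon
    sequencing runs with per-well clonotype ground truth, merges and filters
    paired-end reads, demultiplexes reads to wells through a two-dimensional
    row/column barcode matrix, assigns V and J gene segments, extracts CDR3
    junctions and calls productivity, pairs alpha and beta chains per well and
    computes amplification-efficiency and V-usage tables, designs and
    validates single-vector TCRa-2A-TCRb Gibson expression constructs in
    silico, and classifies antigen reactivity from IL-2 dose-response curves
    by an area-under-curve threshold rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
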