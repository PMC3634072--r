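Package: mirkit
Title: Pre-miRNA Discovery and miRNA Target Prediction from Genomic
    Contigs and Small RNA Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for discovering microRNA precursors in genomic
    contigs of non-model organisms and predicting miRNA targets in
    3'UTRs. Combines de novo hairpin scanning under a simplified
    nearest-neighbour thermodynamic model, homology mapping against a
    reference hairpin catalogue, read-stack evidence of Drosha/Dicer
    processing ("block-like" alignments outside the terminal loop),
    tandem-repeat and ncRNA contaminant filters, and dual-engine target
    prediction (hybridization minimum free energy with extreme-value
    calibrated p-values, and seed-weighted complementarity scoring)
    intersected into consensus targets. Ships a seeded synthetic-data
    generator with ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
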