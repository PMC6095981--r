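Package: isoclonal
Title: Isotype-Resolved B-Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of isotype-resolved, molecularly barcoded B-cell receptor
    (BCR) repertoire sequencing data. Provides a synthetic repertoire and read
    simulator with full ground truth, barcode-consensus error correction with
    pre-correction error-rate estimation, a built-in V/J annotator with
    silent/non-silent somatic hypermutation counting and CDR3 extraction,
    single-mismatch clonal network construction, separation of malignant and
    non-malignant repertoires in chronic lymphocytic leukemia, isotype overlap
    coefficients from fixed-depth subsampling, conditional class-switch
    probabilities given IGHV gene identity and mutational status, and
    isotype-specific IGHV gene usage profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
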