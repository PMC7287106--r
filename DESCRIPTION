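Package: isomiRseq
Title: Canonical miRNA and isomiR Profiling from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and differential-abundance analysis of canonical
    microRNAs and their sequence isoforms (isomiRs) from small RNA sequencing
    reads. Provides a miRBase-style hairpin/mature reference model, an
    offset-aware read-to-hairpin aligner with explicit 5'/3' end shifts,
    non-templated 3' tails and internal substitutions, an isomiR classifier
    and dotted-name nomenclature, counts-per-million expression thresholding
    and abundance shares, a negative-binomial exact test with conditional
    maximum-likelihood dispersion estimation and Benjamini-Hochberg
    correction, strong-modulation selection, cross-cohort concordance
    classification, hypergeometric over-representation, and a synthetic
    small RNA cohort generator with per-read ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
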