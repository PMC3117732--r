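Package: ebTFnet
Title: Empirical Bayes Inference of Transcription-Factor Regulatory Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds topological (genomic versus non-genomic) transcription-factor
    regulatory networks by combining three sources of evidence under one empirical
    Bayes umbrella: a three-population random-effects mixture model for two-condition
    probe-level expression data fitted by EM, position-weight-matrix motif scanning
    calibrated to a local false discovery rate against a high-order Markov background
    null, and ChIP peak intervals with peak-level FDR. Targets are classified as
    direct-binding genomic (DBGA), indirect-binding genomic (I-DBGA) or non-genomic
    (NGA) actions; hub transcription factors are scored with an exact
    Poisson-binomial test; selective estrogen receptor modulator (SERM) responses are
    classified by fold-change rules; and promoter epigenetic signals (PolII,
    H3K4me2, H3K27me3 ChIP-seq and MCIp-seq methylation) are quantified and
    classified into non-responsiveness mechanisms. Synthetic-data generators for
    every input class make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
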