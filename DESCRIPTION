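Package: mirtarscan
Title: Two-Stage Prediction of microRNA Target Sites and mRNA Repression
Version: 0.1.0
Authors@R:
    person("Mira", "Tanawong", email = "mira.tanawong@example.org",
           role = c("aut", "cre"))
Description: Enumerates canonical microRNA seed-match sites (6mer, 7mer-A1,
    7mer-m8, 8mer) in 3'-UTR sequences, computes a 154-dimensional feature
    vector per candidate site (site type, duplex stability, accessibility,
    3'-supplementary pairing, conservation, SNP annotation, and sequence
    descriptors), and trains a two-stage gradient-boosted classifier: a
    site-level binding model with MCC-driven forward stepwise feature
    selection, whose per-site probabilities are aggregated (sum and top-3)
    into transcript-level features for a repression model. Includes curated
    negative-sample filtering against validated interaction lists, 1:1
    under-sampling, expression-threshold labelling, a synthetic-corpus
    generator with ground-truth manifests for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
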