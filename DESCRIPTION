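Package: loopfire
Title: Predicting Promoter Firing from Chromatin Looping Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements fitting-free looping formulae that predict the
    relative firing probability of every active promoter on a chromosome
    from its genomic distance to the nearest active (or nearest genic)
    promoter, following ptrans ~ b(1 + c/l) with a fractal-globule contact
    prior. Provides readers for BED/bedGraph tracks, classification of
    DNase-hypersensitive sites into genic, non-genic and other firing
    states from a ChromHMM-style segmentation, rank-based evaluation
    against nascent-transcription signal (Spearman correlation, decile
    confusion, agreement ratio), a synthetic chromosome and signal
    generator for closed-loop testing, and a desk-scale Brownian-dynamics
    implementation of the underlying bead-and-spring chromatin model with
    switching transcription-factor:polymerase particles for
    cross-validation of the formulae.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
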