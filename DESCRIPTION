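Package: ipgtools
Title: Interaction Profile Groups from Trans Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calls interaction profile groups (IPGs) from binned Hi-C
    contact matrices by spectral decomposition of trans (interchromosomal)
    contact frequencies: cis pixels are masked by resampling, the matrix is
    rescaled to be doubly stochastic, leading eigenvectors (ordered by
    eigenvalue modulus) are clustered with k-means and consolidated into
    functional groups using chromatin tracks. Downstream analytics include
    iterative-correction balancing, distance-decay P(s) curves and their
    log-log derivatives, saddle plots, diamond insulation scores with
    prominence-based boundary calls, observed/expected pileups at oriented
    CTCF sites, two-state Bernoulli and Gaussian hidden Markov model domain
    segmentation, replication-timing processing, rescaled domain stackups,
    and ROC evaluation of signal tracks against group labels. A stochastic
    one-dimensional loop-extrusion simulator with fold-change-weighted CTCF
    capture and release, and a synthetic-genome generator with planted
    group structure, make every stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
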