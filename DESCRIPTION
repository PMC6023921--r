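Package: iahctools
Title: Single-Cell Dissection of Intra-Aortic Haematopoietic Cluster Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for CEL-Seq single-cell UMI data from the mouse
    aorta-gonad-mesonephros region: in silico purification of intra-aortic
    haematopoietic cluster (IAHC) cells by marker transcript thresholds, exact
    UMI downsampling normalization, k-medoids clustering and minimum-spanning-tree
    pseudotime ordering of the endothelial-to-haematopoietic transition, a
    negative-binomial Wald test applied in sliding windows along pseudotime,
    transcription-factor temporal-program clustering and correlation networks,
    and a stochastic swap-search deconvolution that resolves whole-IAHC bulk
    transcriptomes into their constituent single cells.  A synthetic-data
    generator emulates the study design (cell populations, opposing marker
    gradients, temporal TF archetypes, pseudo-bulk clusters of known membership)
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    cluster,
    grDevices,
    graphics,
    igraph,
    methods,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
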