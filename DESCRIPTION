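Package: mdgraphvae
Title: Microbe-Drug Association Prediction with a Graph Variational
    Autoencoder and Random Forest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate microbe-drug associations from a known
    bipartite association matrix, microbial marker sequences and drug
    structural similarities.  Sequence similarity (Smith-Waterman local
    alignment), Gaussian interaction-profile kernels and precomputed
    structural similarities are fused, smoothed and thresholded into
    per-entity feature graphs; a variational graph autoencoder with a
    collapsed-weight graph convolution learns low-dimensional node
    embeddings, which a multi-head graph attention stage refines on the
    bipartite association graph; a random-forest classifier scores
    candidate pairs by tree vote share.  Includes a synthetic-data
    generator with planted block structure, k-fold cross-validation
    with leakage control, ROC/PR metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    randomForest,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
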