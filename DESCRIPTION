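Package: mdlink
Title: Microbe-Disease Association Prediction on Bidirectional Weighted
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved disease-microbe associations from a sparse
    binary bipartite network. Gaussian interaction-profile kernels provide
    similarity networks for microbes and diseases; an asymmetric edge
    normalization and a node-weight diagonal turn the heterogeneous network
    into a bidirectional weighted graph; a neighbor-based bidirectional
    recommendation step densifies the sparse adjacency; and truncated
    KATZ-style propagation over walks of fixed length scores every
    disease-microbe pair. Includes leave-one-out and repeated k-fold
    cross-validation with ROC/AUC, a planted-block synthetic data generator,
    and a command-line interface for simulation, prediction and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
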