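Package: acpgcn
Title: Graph Convolutional Networks for Anticancer Peptide Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies peptides as anticancer (ACP) or non-ACP by representing
    each amino-acid chain as a path graph whose nodes carry four concatenated
    attribute embeddings (one-hot, node2vec positional embeddings, and two
    binary physicochemical property encodings), and feeding the graph through a
    three-branch graph neural network: a stacked graph convolution branch, a
    differentiable graph-collapse pooling branch, and a residual graph
    convolution branch, fused by a fully connected head. Includes a synthetic
    labelled-peptide generator, stratified cross-validation, independent-test,
    ablation and class-ratio experiment harnesses, the standard metric suite
    (sensitivity, specificity, precision, accuracy, MCC, F1, AUC), TU-format
    graph-dataset input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
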