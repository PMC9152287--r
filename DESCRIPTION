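Package: mirdap
Title: miRNA-Disease Association Prediction from Network Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts disease-associated miRNAs from two miRNA networks: a
    weighted functional-similarity network and a bipartite miRNA-mRNA
    interaction network. Each network is embedded with second-order biased
    random walks (node2vec) trained by skip-gram with negative sampling;
    per-network 512-dimensional vectors are fused into 1024-dimensional
    miRNA features, encoded by a small convolutional network trained with
    backpropagation, and classified by Gaussian naive Bayes on the 256-d
    intermediate code. Includes a positive-unlabeled evaluation harness
    (negative sampling at configurable ratios, stratified five-fold
    cross-validation, ROC-AUC / PR-AUC / F1), layer-ablation variants,
    candidate ranking, and a synthetic benchmark generator with planted
    similarity-community and shared-target signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
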