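Package: fbnfuse
Title: Multiview Functional Brain Network Fusion by Joint Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-subject functional brain networks (FBNs) from ROI
    time series by four complementary strategies (Pearson correlation, sparse
    representation, mutual information, and correlation's correlation), stacks
    the resulting multiview networks into a third-order tensor, and learns a
    joint ROI embedding by regularized alternating-least-squares bilinear
    (RESCAL-type) tensor factorization. A fused FBN is reconstructed from the
    embedding and evaluated with a nested leave-one-out cross-validation
    protocol using t-test feature selection and a linear support vector
    machine. Includes seed-deterministic synthetic cohort and tensor
    generators for end-to-end testing without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
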