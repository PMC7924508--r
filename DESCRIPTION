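Package: riskembed
Title: Jointly Optimized Supervised Autoencoder Embeddings for Imbalanced
    Clinical Risk Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionality reduction and classification learned jointly for
    imbalanced tabular clinical-risk data. Implements denoising autoencoder
    embeddings whose reconstruction target can be the identity (semi-supervised
    regularization) or a label-dependent mapping (symmetry or zero mapping,
    which pushes healthy records toward the origin of the decoded space),
    trained with a joint cross-entropy plus weighted reconstruction loss,
    PReLU activations, an optional bypass connection into the classifier head,
    L1-sparse embeddings and RMSProp with early stopping. Includes the
    preprocessing pipeline for questionnaire-style risk-factor tables
    (answered-flag encoding, one-of-K indicators, train-fold mean imputation
    and [0,1] scaling), a synthetic cohort generator, stratified and nested
    cross-validated grid search scored by precision-recall AUC, paired t-test
    model comparison, and perturbation-based interpretation of the embedding
    with agglomerative feature clustering.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
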