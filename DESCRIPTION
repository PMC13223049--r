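Package: sonosex
Title: Ultrasound-Based Sex Classification Pipeline for Abalone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for sex classification of abalone from
    gonadal ultrasound images: a synthetic speckle-phantom generator with
    per-individual latent anatomy, overlay stripping and threshold-based
    region-of-interest extraction, individual-level (leakage-free) dataset
    partitioning with offline balancing augmentation, a PCA plus logistic
    regression baseline selected on balanced accuracy, custom forward and
    reverse ("double compression") convolutional network families trained
    with binary cross-entropy and early stopping, confusion-matrix
    evaluation, and feature-space diagnostics (k-means with elbow and
    silhouette selection, t-SNE embedding, activation maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
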