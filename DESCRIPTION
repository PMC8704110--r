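Package: somnia
Title: Ensemble Prediction of Self-Disclosed Insomnia from Microblog Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying self-disclosed insomnia in short social-media
    text. Provides a calibrated synthetic cohort generator (user labels,
    gender, Big 5 trait vectors, and token streams with planted
    class-conditional category effects), tweet cleaning with seed-phrase
    removal to prevent label leakage, psycholinguistic category scoring
    against open JSON lexicons, deterministic feature-hashing sentence
    embeddings, Fisher-criterion feature selection with collinearity pruning,
    a suite of base classifiers evaluated under repeated stratified
    cross-validation, a double-weighted convex-combination ensemble whose
    weights derive from split-wise root-mean-square error (W = 1 - RMSE),
    and descriptive analyses: ROC/AUC, trait-bin distributions, 2x2
    chi-square association tests, and collapsed-Gibbs latent Dirichlet
    allocation topic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    e1071,
    randomForest,
    kernlab,
    rpart,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
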