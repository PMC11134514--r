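Package: taskhardness
Title: Task Hardness Estimation for Few-Shot Bioactivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how hard a bioactivity-prediction task is for
    knowledge-sharing (meta-learning) methods, given a collection of source
    tasks. Hardness combines three components: external chemical-space
    hardness from the optimal transport dataset distance (OTDD) between
    labeled molecule sets, external protein-space hardness from embedding
    distances between protein sequences, and internal hardness from the
    few-sample error of single-task classifiers. Includes an exact
    transportation-simplex and an entropic (Sinkhorn) optimal-transport
    solver, the closed-form 2-Wasserstein (Bures) distance between Gaussian
    label models, a desk-scale prototypical network for validating that
    hardness anti-correlates with meta-learning gain, rational source-task
    selection, and a synthetic task-universe generator with planted
    inter-task relatedness for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    class,
    pROC,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    optparse,
    clue
Config/testthat/edition: 3
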