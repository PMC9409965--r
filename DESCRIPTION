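Package: robustcheck
Title: Robustness Evaluation for Biomarker Classifiers on Tabular Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate the robustness of already-developed machine
    learning classifiers built from tabular omics measurements such as
    metabolite concentrations. Provides a factor-analysis feature screen
    (leave-out false-discovery-rate filtering, Horn's parallel analysis,
    factor-loading clustering with silhouette-based pruning, and a logistic
    variance screen), feature-level noise corruption engines (replacement
    noise and dampened additive Gaussian noise), Monte Carlo noise-severity
    sweeps and train/test-split studies that quantify the mean and variance
    of classifier accuracy and parameter values, a tolerable-noise estimator
    based on the linear accuracy-decay model, and a seeded generator of
    two-class synthetic datasets with planted informative features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    e1071,
    randomForest,
    glmnet,
    car,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
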