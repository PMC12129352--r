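Package: plasmodebench
Title: Comparing Parametric and Plasmode Simulation for Classifier Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A meta-simulation framework for judging when Plasmode simulation
    (resampling covariates from a fixed base dataset combined with a specified
    outcome-generating model) is preferable to fully parametric simulation in
    method-comparison studies of binary classifiers. Provides a mixed-marginal
    Gaussian-copula (NORTA) data-generating process with randomly drawn normal,
    log-normal, bimodal and contamination marginals, a calibrated logistic
    outcome-generating model, controlled misspecifications of both, a
    five-classifier benchmark under nested stratified cross-validation with
    random-search tuning and fallback handling, and evaluation of each
    simulation strategy by estimation error, ranking fidelity (normalized
    Kendall distance) and the proportion of acceptable results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
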