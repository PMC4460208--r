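Package: dissolvegp
Title: Symbolic Regression and Neural Surrogates for Drug Dissolution Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns measured drug-dissolution profiles of solid lipid
    extrudates into compact closed-form release equations. Implements the
    full empirical-modeling workflow: dataset preprocessing (noising,
    output balancing, linear scaling, leave-one-formulation-out splitting,
    surrogate-model design-space augmentation), multilayer-perceptron
    training with momentum, delta-bar-delta adaptive learning rates and
    jog-of-weights restarts, derivative-based input-sensitivity screening,
    tree-based genetic-programming symbolic regression (direct, and
    indirect through the Weibull dissolution model), multistage
    simulated-annealing plus local-optimizer parameter fitting, and the
    standard evaluation metrics (RMSE, the FDA f2 similarity factor, and
    per-parameter coefficient of variation across cross-validation folds).
    A synthetic-data generator reproduces the study design of five
    extrudate formulations sampled every five minutes up to 1000 minutes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
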