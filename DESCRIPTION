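Package: spikedecode
Title: Machine-Learning Decoding of Behavioural Variables from Neural Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for decoding continuous behavioural variables (cursor
    velocity, animal position) from populations of spiking neurons. Bins
    spike trains and outputs onto a common time grid, builds lagged design
    matrices and sequence tensors, and fits eleven decoder families: Wiener
    filter, Wiener cascade, support vector regression, gradient-boosted
    trees, feedforward and recurrent (simple RNN, GRU, LSTM) neural
    networks, a Kalman filter with a kinematic latent state, a Naive Bayes
    population decoder with Poisson tuning curves, and a stacked ensemble.
    Evaluation follows contiguous-block nested cross-validation with
    fraction-of-variance R-squared, a fold-correlation-corrected standard
    error, block-bootstrap confidence intervals, and pluggable
    hyperparameter search (grid, random, Gaussian-process Bayesian
    optimization). A synthetic-data module generates cortical-like
    (cosine-tuned) and hippocampus-like (place-field) Poisson spiking
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    e1071,
    xgboost,
    lhs,
    readr
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
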