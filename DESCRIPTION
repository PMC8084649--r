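Package: srcal
Title: Sparse Representation Classification with Analytic Dictionary
    Learning for Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting treatment response from cardiopulmonary
    exercise testing (CPET) time series with sparse representation
    classifiers. Implements orthogonal matching pursuit, overcomplete
    discrete-cosine (DCT) dictionaries refined by K-SVD dictionary
    learning, the classic minimum-class-residual sparse representation
    classifier (SRC) and its label-augmented analytic-dictionary variant
    (SRC-AL), a blood-pressure-change clinical baseline and responder
    labeling for antihypertensive aerobic exercise programs, a synthetic
    CPET-like data generator, UCR-style time-series file input/output,
    and a leave-one-out cross-validation harness with confusion-matrix
    metrics and sparse-factor grid search.
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
    MASS,
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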