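Package: retest
Title: Test-Retest Reliability of Multi-Scanner Task Measures via
    Bayesian Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying test-retest reliability of task-evoked
    measures collected across repeated sessions on multiple scanners.
    Implements per-unit (voxel or region) intraclass correlation
    coefficients from Bayesian-regularized linear mixed-effects variance
    decomposition in absolute-agreement ICC(2,1) and consistency ICC(3,1)
    formulations, an integrative Bayesian multilevel model that pools all
    brain regions in a single MCMC fit and yields per-region posterior ICC
    distributions with partial pooling, behavioral psychometric metrics
    for face-emotion tasks (four-parameter logistic choice curves,
    reaction-time morph slopes, visual-search set-size slopes, quality
    control exclusion rules), temporal signal-to-noise summaries, and a
    synthetic-data generator that reproduces the crossed subjects x
    sessions x scanners x regions design the estimators assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
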