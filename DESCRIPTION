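Package: wcstbayes
Title: Bayesian Cognitive-Agent Modelling of the Wisconsin Card Sorting Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A generative Bayesian cognitive-agent model of trial-by-trial
    behaviour in the Wisconsin Card Sorting Test (WCST). Simulates agents that
    infer the hidden sorting rule by recursive Bayesian belief updating with a
    feature-activation process governed by two cognitive parameters,
    flexibility and information loss. Provides information-theoretic
    trajectory reconstruction (Bayesian surprise, Shannon surprise, predictive
    entropy), Heaton-style clinical scoring (perseverative and
    non-perseverative errors, trials to first category, failures to maintain
    set), exact trial-wise likelihood evaluation with a gridded posterior over
    the two parameters, and simulation-based validation of parameter recovery
    (RMSE, R-squared, coverage calibration, simulation-based calibration rank
    histograms).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
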