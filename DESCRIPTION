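Package: mfpdx
Title: Multivariable Fractional Polynomial Models with Influential-Point
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Gaussian multivariable regression models with fractional
    polynomial (FP) functions for continuous covariates.  Implements the
    function selection procedure (a three-step closed test over the FP1/FP2
    grid), backward elimination cycled to convergence (MFP), and case-deletion
    influence diagnostics for function selection: leave-one-out and
    leave-two-out deviance-difference scans, univariable and multivariable
    screening pipelines, and grouped pair summaries.  Includes a calibrated
    plasmode-style synthetic data generator with a known true model for
    studying replicability and sample-size effects, plus tidy accessors and
    ggplot2 visualisations throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
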