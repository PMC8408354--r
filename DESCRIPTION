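Package: ivsamp
Title: Internal-Validation Sampling Strategies for Exposure Measurement-Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo machinery for studying how the design of an internal
    validation sample (random, stratified random, or extremes sampling on the
    error-prone measure) interacts with regression-calibration corrections for
    covariate measurement error in linear models. Provides a synthetic
    cohort generator (gold-standard exposure with skewness-controlled gamma
    residuals, an error-prone substitute under linear, nonlinear and
    differential error models, confounders and a continuous outcome), the
    three sampling strategies, five analysis methods (uncorrected,
    validation-sample-restricted, standard, validation and efficient
    regression calibration with delta-method standard errors), a full-factorial
    simulation engine with Monte Carlo standard errors, and summaries of
    mean-squared-error efficiency gains between sampling designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
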