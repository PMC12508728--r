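Package: hydromark
Title: Dynamic Hydration-Response Modelling of Quantitative Liver and Spleen MRI Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transient response of quantitative MRI markers of the
    liver and spleen to an ingested isotonic drink as a first-order linear
    time-invariant system. Provides closed-form responses to delayed step,
    rectangular and trapezoidal inputs with a Runge-Kutta reference
    integrator, bounded multi-start nonlinear least-squares estimation of the
    dynamic parameters from longitudinal region-of-interest time series,
    a study-shaped synthetic cohort generator, descriptive maximum-change
    statistics with paired t-tests, linear mixed models for covariate
    evaluation, and an end-to-end pipeline producing tabular summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    lmerTest,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
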