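Package: emadsem
Title: Dynamic Structural Equation Models for Experience-Sampling Affect Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for intensive longitudinal (experience-sampling / ecological
    momentary assessment) studies of stress and affect: long-format data
    validation and equal-interval time gridding with phantom occasions,
    instrument scoring (PANAS, UCLA loneliness, essential resilience scale)
    with reliability statistics, a forward simulator for a two-level AR(1)
    dynamic structural equation model with latent person-mean centering and
    cross-level trait moderation, a conjugate Gibbs sampler for that
    model with convergence diagnostics, and post-estimation reporting
    (descriptives, standardized effects, within/between R-squared, rendered
    summary tables).
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
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
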