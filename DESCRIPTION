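Package: canopytemp
Title: Temperature-Response Decomposition of Canopy-Height Growth in Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes high-frequency canopy-height time series from multi-year
    wheat field trials into a temperature-responsive component (the slope of the
    stem-elongation-rate versus temperature regression), a temperature-irresponsive
    vigour component (the regression intercept evaluated at the critical temperature
    at which slope and intercept decorrelate across plots), and phase-timing traits
    (thermal time to 15% and 95% of final height, elongation duration, final height).
    Includes spatial correction of augmented field designs with tensor-product
    P-splines, genotype-by-year variance components and broad-sense heritability by
    REML, trait correlations, final-height prediction models with type II ANOVA, and
    a synthetic field-trial generator with known genotype-level ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
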