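Package: reefpulse
Title: Coral Bleaching Response and Thermal-History Analysis for
    Photo-Quadrat Reef Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for coral-reef bleaching
    surveys on equatorial atolls. Scores bleaching severity from benthic
    photo-quadrat point counts via a bleaching response index (BRI),
    derives degree-heating-week (DHW) heat-stress metrics and historical
    sea-surface-temperature variability metrics from weekly SST series,
    quantifies local human disturbance from village population data, and
    runs the inference chain used in reef resilience studies:
    Bonferroni-screened univariate regressions, shrinkage-spline
    generalized additive models compared by second-order AICc and
    analysis of deviance, Bray-Curtis non-metric multidimensional
    scaling, sequential-sums-of-squares PERMANOVA, and a Monte Carlo
    analysis of photo-quadrat sampling sufficiency. A seeded
    synthetic-data generator emulates ENSO-modulated SST regimes,
    severity-graded bleaching surveys, and disturbance-structured coral
    communities so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
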