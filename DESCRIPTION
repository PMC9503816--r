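Package: weartime
Title: Minimum Wear-Duration Analysis for Free-Living Gait and Postural Sway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines how many days of wearable accelerometer monitoring are
    needed to capture gait and postural-sway impairment and its variability in
    free-living cohorts. Implements a three-stage reliability framework
    (rank-sum difference testing against a baseline wear duration, two-way
    consistency intraclass correlation ICC(C,k), and stability of Spearman
    correlations with patient-reported measures), bout-level computation of 13
    postural-sway metrics and 14 temporal, asymmetry and stability gait
    metrics, percentile-based sway bout filtering, a days-required regression
    on observation count and coefficient of variation, bootstrap power
    analysis, and a hierarchical synthetic cohort generator with closed-form
    reliability curves for validating every stage without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
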