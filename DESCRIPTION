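Package: sparctug
Title: Movement Smoothness Analysis for the Instrumented Timed Up and Go Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for waist-worn inertial measurement unit (IMU)
    recordings of the Timed Up and Go (TUG) test. Reads delimited-text IMU
    exports, gates recordings at movement onset, segments the test into its
    phases from integrated yaw and pitch angles, computes the spectral arc
    length (SPARC) smoothness metric per channel and phase, a frequency-ratio
    freezing-of-gait index, and cohort-level statistics (two-way group-by-trial
    ANOVA with Type II sums of squares and Sidak-adjusted post-hoc contrasts,
    Pearson correlation maps against clinical scores, Cohen effect sizes, and
    noncentral-t power and sample-size calculations). Includes a seeded
    synthetic-cohort generator that emulates control-like and
    Parkinson's-disease-like TUG trials with ground-truth segmentation and
    co-simulated clinical scores, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
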