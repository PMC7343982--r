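Package: cyclobiome
Title: Longitudinal Vaginal Microbiome Dynamics over the Menstrual Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily-resolution vaginal microbiome time
    series: community state type (CST) assignment and long-term transition
    detection with an exact Poisson-binomial test of their association with
    menses; Shannon diversity, Bray-Curtis and Jensen-Shannon dissimilarities
    and the log Jensen-Shannon rate-of-change stability statistic; menstrual
    cycle day normalization with loess trajectories and correlation against a
    reference estradiol curve; least-squares (Lomb-Scargle) spectral analysis
    of unevenly sampled series; lifestyle covariate statistics (nutrient
    proportions, exercise, mood, vegetarian contrast via a stratified rank
    test, subject-stratified PERMANOVA); and a seeded synthetic daily-cohort
    generator that emulates the statistical structure such studies assume, so
    every stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
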