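Package: turnvar
Title: Turn-Bias Variability and Behavioral Predictability in Y-Maze Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores left/right turn decisions from Y-maze centroid
    trajectories, summarizes per-individual turn bias and locomotor
    activity, and quantifies inter-individual behavioral variability with
    the raw (unscaled) median absolute deviation of turn-bias scores.
    Group differences in variability are tested with label-permutation
    tests and fly-level percentile bootstrap intervals; companion
    comparisons (one-way ANOVA on turn bias with residual diagnostics,
    Kruskal-Wallis and Benjamini-Hochberg-corrected pairwise Mann-Whitney
    tests on turns per minute) are included. A hierarchical Beta-Bernoulli
    cohort simulator with lognormal turn rates generates synthetic
    three-group experiments for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
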