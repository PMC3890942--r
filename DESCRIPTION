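Package: pcrossing
Title: Simulation and Analysis of the Perceptual Crossing Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying minimal dyadic social interaction in the
    perceptual crossing paradigm: a simulator for pairs of agents moving
    avatars along a wrap-around one-dimensional space with tactile-only
    contact feedback, and the complete analysis pipeline for such trials.
    Includes contact-event segmentation, click-target attribution,
    a turn-taking statistic on binary movement series, trial and team
    scoring, per-contact click probabilities, subjective-rating summaries,
    variance-gated one-tailed t-tests, and a click-synchrony randomization
    analysis, with tidy data frames throughout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
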