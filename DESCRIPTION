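Package: ovibout
Title: Ethogram Bout Analysis of Drosophila Egg-Laying Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the Drosophila melanogaster egg-laying
    motor programme from frame-based behaviour annotations. Reads and
    validates bout-level event tables, computes per-fly bout metrics
    (inter-egg intervals, binned bout counts, per-egg normalisation, bout
    durations, egg-burial proportions), peri-event behaviour-probability
    curves aligned to egg expulsion, first-order Markov transition matrices
    between egg-laying phases, and optogenetic stimulus-locked metrics.
    Includes a seeded semi-Markov ethogram simulator with ground truth for
    parameter-recovery testing, and an automated two-group test-selection
    procedure (normality- and variance-gated t, Welch t, Mann-Whitney and
    Fisher exact tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
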