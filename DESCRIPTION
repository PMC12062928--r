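Package: playmimicry
Title: Rapid Facial Mimicry and Play Dynamics from Behavioral Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethology of primate social play from
    long-format behavioral event logs: detection of rapid facial mimicry
    (congruent replication of a play face or full play face within one
    second), perception-condition contingency analysis with a mixed-model
    design-table contract, play asymmetry and Shannon diversity indices on
    sequential four-pattern windows, five-way session-condition
    classification with time-remaining and midpoint analyses, the
    accompanying exact and Monte-Carlo nonparametric tests, FACS/OpenFace
    action-unit summaries, and a synthetic dyadic play-session generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
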