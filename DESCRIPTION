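Package: pacedraft
Title: Drafting and Pacing Strategy Models for Elite Marathon Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the aerodynamics and energetics of drafting in elite
    marathon running. Provides running-power models for elite runners,
    quadratic drag-versus-speed curves per drafting formation and position,
    per-runner energy ledgers computed from race split tables, and an
    energy-conserving three-phase race-time optimizer that projects how fast
    a race could have been run with better drafting formations and a
    positive-splitting pacing strategy. Ships transcriptions of the 2018 and
    2022 Berlin marathon splits and a synthetic-scenario generator so the
    full pipeline runs without external data.
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
    lhs,
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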