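Package: ventrl
Title: Safe Offline Reinforcement Learning for Ventilator Settings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline reinforcement-learning pipeline for ICU ventilator
    decision support. Builds hourly patient trajectories from long-format
    event tables, shapes clinical rewards that combine gas-exchange changes
    (P/F ratio, dead-space fraction) with terminal outcomes (mortality,
    length of stay, discharge destination) under a tunable weighting, trains
    dueling double deep Q-networks with prioritised experience replay,
    derives greedy and king-knight-restricted policies over a PEEP-by-FiO2
    action grid, evaluates them with per-decision weighted importance
    sampling, weighted doubly robust and MAGIC off-policy estimators, screens
    policies for reward-shaping robustness via cross off-policy evaluation,
    and inspects selected policies with the delta-Q metric, aggregate action
    surfaces and per-trajectory alerts. Ships a seeded synthetic ICU cohort
    simulator for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
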