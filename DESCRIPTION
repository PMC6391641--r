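Package: incentr
Title: Financial-Incentive Adjudication Engine for Remote Weight-Loss Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A near-real-time contingency-management engine for weight-loss
    trials that pay participants for verified weekly behaviors. Ingests
    time-stamped home weigh-in streams and daily calorie-log records,
    applies a same-day anti-gaming quality-control filter, adjudicates
    dietary self-monitoring and weight-loss criteria each week under a 2x2
    factorial incentive design, computes payouts under a capped escalating
    schedule, composes loss-framed notification messages, and tracks
    payments through a staff-review ledger. A synthetic cohort simulator
    with ground truth makes the whole pipeline testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
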