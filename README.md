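# incentr

A financial-incentive adjudication engine for remote weight-loss trials
that pay participants weekly for objectively verified behaviors
(contingency management). It is written for trialists and digital-health
engineers who run — or simulate — studies in which participants log
calories in a diet app and weigh in on a cellular home scale, and an
automated weekly batch decides who earned money, how much, and what the
notification text says.

## What it computes

Each enrollment-anchored week *w* = [*e* + 7(*w*−1), *e* + 7*w*) days, per
participant, the engine adjudicates two criteria under a 2×2 factorial
design (group 1: paid for both; group 2: diet only; group 3: weight only;
group 4: unpaid control):

- **Dietary self-monitoring** — met iff ≥ 5 days have a logged total
  ≥ 1000 kcal (women) / 1200 kcal (men), including ≥ 1 weekend day.
- **Weight loss** — met iff Δ = *w*first − *w*last > 0 over the week's
  *retained* weigh-ins (≥ 2 readings required). Before adjudication, a
  same-day gaming filter removes every reading of any participant-day
  whose relative spread (max − min)/min exceeds 10% strictly — discordant
  same-day weights suggest a proxy weigher.

Payouts come from a capped escalating schedule (≤ $28/week, ≤ $300/study,
$2 weekly floor in cohort 3; the combined arm earns half per singular
behavior), missed weeks trigger a loss-framed text ("you would have earned
$X"), and every payment walks a staff-review ledger
(computed → approved/edited/denied → scheduled → paid) with a one-day
institutional delay. A synthetic cohort simulator with per-week ground
truth makes the entire pipeline testable without real data.

## Worked example

Simulate a small two-cohort study, run QC and week-2 adjudication, and
stage the ledger:

```r
library(incentr)

study <- study_config()                      # 24 weeks, default schedule
sim   <- simulation_config(seed = 7, cohort_sizes = c(6L, 6L))
d     <- generate_cohort(sim, study)

qc  <- incentr:::qc_filter_stream(d$weighins, 0.10, study$study_timezone)
res <- run_week(d$roster, d$diet, qc$events, week = 2, config = study)
res[, c("participant_id", "diet_met", "weight_met",
        "amount_earned_cents", "amount_foregone_cents")]
#>   participant_id diet_met weight_met amount_earned_cents amount_foregone_cents
#> 1 P001           FALSE    NA                           0                   500
#> 2 P002           NA       FALSE                        0                   500
#> 3 P003           FALSE    TRUE                       250                   250
#> 4 P004           NA       NA                           0                     0
#> 5 P005           NA       TRUE                       500                     0
#> ...
```

`NA` marks a criterion the participant's arm is not paid for; week 2 of
the default schedule is worth $5, so P003 (combined arm, lost weight but
under-logged) earns half and foregoes half, while P005 (weight-only arm)
earns the full $5. Earned + foregone always reconstructs the week's
attainable maximum. The loss-framed text for a missed week reads:

```r
compose_weekly_message(res[res$scenario == "missed", ][1, ], group = 2,
                       study$messaging)$body
#> You did not log your food this week. If you had, you would have earned $5.
```

and staging keeps only the positive payouts for staff review:

```r
stage_ledger(res, at = as.POSIXct("2016-03-21 17:00", tz = "America/New_York"))
#>   participant_id  week amount_cents state
#> 1 P003               2          250 computed
#> 2 P005               2          500 computed
#> 3 P012               2          500 computed
```

A command-line wrapper for the weekly batch
(`simulate` / `adjudicate` / `ledger`) ships in
`inst/scripts/incentive_pipeline.R`; an example YAML study configuration
is in `inst/extdata/study_config.yaml`.

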