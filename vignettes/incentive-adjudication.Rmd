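---
title: "Adjudicating weekly financial incentives from home weigh-in and diet-log streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating weekly financial incentives from home weigh-in and diet-log streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incentr)
```

## The problem

Contingency management pays participants for objectively verified target
behaviors. In a remote weight-loss trial the two verifiable behaviors are
*dietary self-monitoring* (daily calorie logging in a diet app) and
*interim weight loss* (measured on a cellular home scale that transmits
every reading). `incentr` is the adjudication engine for such a trial: it
ingests the two raw event streams, screens the weigh-ins for gaming,
decides each week whether each participant earned an incentive and how
much, composes the notification text, and tracks the payment through a
staff-review ledger.

The study design it implements is a 2×2 factorial: group 1 is paid for
both behaviors, group 2 for self-monitoring only, group 3 for weight loss
only, and group 4 is an unpaid control that still receives weekly
encouragement texts. Three cohorts (n = 34, 31, 31; N = 96) enroll
sequentially over a 24-week program.

## The weekly criteria

* **Diet**: a day *qualifies* when its logged calorie total reaches the
  sex-specific threshold — 1000 kcal for women, 1200 kcal for men
  (deliberately below typical weight-loss targets, so the *process* of
  honest logging is rewarded rather than the calorie value itself). The
  week is met with ≥ 5 qualifying days including at least one Saturday or
  Sunday. Of the 2⁷ = 128 possible day patterns, exactly 28 satisfy the
  rule — the test suite checks this by brute-force enumeration against an
  independently written restatement of the rule.
* **Weight**: the change is *first minus last* retained reading of the
  enrollment-anchored week; any strictly positive loss counts. A week is
  *evaluable* only with ≥ 2 retained readings at distinct times — hence
  the instruction to weigh at least twice weekly.

`evaluate_diet_criterion()` treats "weekend" as Saturday/Sunday of the
participant-local (study-timezone) calendar date. Zero weight change is
*not* loss: the comparison is strict.

## Gaming QC

A home scale can be gamed by a proxy weigher or by partial weight-bearing.
Readings by different people on the same day are discordant, so for each
participant-day the filter computes the relative spread
$(\max w - \min w)/\min w$ and, when it exceeds 10% *strictly*, removes
**all** of that day's readings — with discordant readings there is no way
to attribute any single one to the participant. Three choices here were
genuinely open and are fixed as follows:

* **Denominator**: the day's minimum weight. It is the most sensitive
  (conservative) choice; a max- or mean-denominator spread is smaller for
  the same pair of weights.
* **Inclusivity**: strictly greater than the threshold. A pair exactly 10%
  apart is retained.
* **Scope**: day extremes rather than consecutive-pair differences; with
  at most a handful of readings per day the two interpretations only
  differ when three or more readings straddle the threshold pairwise, and
  day extremes give the simpler invariant (idempotence is immediate).

The filter is monotone in the threshold, partitions its input, and is
idempotent; all three are property-tested, and the filter is checked
against brute-force pairwise comparison on every same-day multiset of up
to four readings over a weight grid.

## Weeks, time, and money

* **Week anchoring** is per-participant from the enrollment date: week
  $w$ is the half-open interval $[e + 7(w-1), e + 7w)$ days. Cohorts
  enroll months apart, so calendar weeks would misalign arms; a cut-off
  hour is avoided entirely by using whole study-timezone days.
* **Timezone**: one configurable IANA zone (default `America/New_York`,
  the single-site default) defines calendar days for the QC filter, the
  weekend rule, and week windows.
* **Money is integer cents** everywhere. Caps are then exact: no payout
  rounding can leak past the $300 study cap or the $28 weekly maximum.

## The incentive schedule

The trial's published envelope fixes only: at most \$28 in a week, \$300
over the study, and a \$2 weekly floor in cohort 3. Weekly amounts
themselves were never published, so the default schedule fills the
envelope with a nondecreasing ramp (in dollars)

```
5 5 5 5 · 8 8 8 8 · 10 10 10 10 · 12 12 12 12 · 17 17 17 17 · 20 20 · 24 · 28
```

which sums exactly to \$300. Escalating reinforcement is the standard
contingency-management shape (later abstinence/adherence is harder, so it
pays more); any schedule satisfying the envelope invariants can be
supplied instead and is validated by `incentive_schedule()`.

Payout rules, per week:

* Group 2 earns the week's diet component iff the diet criterion is met;
  group 3 the weight component iff weight is lost. The two components are
  equal by default.
* Group 1 (both behaviors) earns **half of each component** per criterion
  met — the study capped all three incentive arms at the same total, so
  the combined arm gets half per singular behavior. Halving is integer;
  an odd cent goes to the diet half, deterministically.
* The cohort-3 \$2 floor is paid unconditionally to incentive arms, and
  the weekly total is then clamped at the weekly cap — so the attainable
  weekly range is \$0 (or \$2 in cohort 3) to \$28 in every cohort.
* Earned amounts are finally truncated against the \$300 cumulative cap.
  The *foregone* amount — what a missed week "would have earned" — is the
  week's attainable maximum minus the pre-truncation earned amount, so
  earned + foregone always reconstructs the week's maximum.

## Messaging

Weekly outcome texts are written once for every scenario, and every
reachable rendering must fit one SMS (160 characters); an oversized
rendering is a configuration error, never a silent truncation. Earned
texts congratulate the behavior(s) met and state the amount added to the
debit card. Missed texts are deliberately **loss-framed**: they state the
amount the participant *would have earned*, exploiting loss aversion.
With the longest behavior phrase ("log your food or lose enough weight",
the combined arm) a third closing sentence would push the missed message
past 160 characters, so the default template keeps exactly the two
loss-framing sentences. Whole-dollar amounts render as `$28`, fractional
ones as `$13.50`.

Cohorts 2–3 additionally receive two encouragement/skill-tip texts per
week, cycled deterministically through a configurable library (tip
wording is trial content, not engine logic; a placeholder library ships
for testing). Session reminders go to **all** arms identically, one per
biweekly in-person session.

## The payment ledger

Payments were human-in-the-loop: staff reviewed each computed incentive
(*approve*, *edit*, or *deny*), and institutional money-transfer approval
delayed the cash by about a day after the notification text. The ledger
is an explicit state machine,

```
computed → approved | edited | denied;  approved/edited → scheduled;  scheduled → paid
```

with a monotone timestamp chain, cap-aware edits, a configurable payment
delay (default 24 h), and hold-not-schedule behavior for any entry that
would push a participant past the study cap. The review UI is replaced by
a CSV of actions, which keeps the human step scriptable: replaying the
same action log always reconstructs the identical ledger.

## The synthetic cohort

No real participant data ship with the package; `generate_cohort()`
creates a cohort with exactly the behavioral structure the engine
assumes, plus a ground-truth table computed during generation by applying
the criterion definitions to the generated streams.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| cohort sizes | 34/31/31 | the trial's enrollment |
| `p_log_day` | Beta(6, 2) | mean 0.75 ≈ 5.25 logging days/week, heterogeneous across participants |
| `p_weigh_day` | Beta(5, 3) | mean 0.625 ≈ 4.4 weigh days/week, near the reported ~5.4 among regular weighers with a long lower tail |
| `kcal_when_logging` | N(1400, 250) kcal | straddles both sex thresholds so qualifying days are common but not certain |
| `adherence_drift` | −0.02 logit/week | participation declines slowly over 24 weeks |
| `true_loss_rate` | 0.25 kg/week in diet-adherent weeks | ~1–2 lb/month, a realistic behavioral-intervention loss rate |
| `baseline_weight` | N(105, 15) kg | BMI ≥ 30 recruitment |
| `weight_noise_sd` | 0.4 kg | day-to-day hydration/clothing variation |
| `gaming_rate` | 0.01/day | rare proxy weigh-ins; injected readings are the day minimum × U(1.1, 1.5), so the QC filter must fire |
| `dropout_hazard` | 0.01/week | ~20% attrition over 24 weeks |

These are loosely calibrated synthetic choices, not estimates: the
simulator exhibits between-participant heterogeneity, declining
engagement, dropout and rare gaming, but has **no** incentive→behavior
feedback loop, no device failures or transmission gaps, no intra-day
multiple genuine weigh-ins, and independent Bernoulli days rather than
streaks. Passing tests therefore demonstrate that the engine implements
its rules exactly on data with this structure — not that the rules
themselves change behavior, which only the trial can show.

All randomness flows from one seed through a locally scoped generator
(the session RNG is saved and restored), so a fixed seed reproduces the
dataset byte for byte.

## Numerical and degenerate-input choices

* Strict comparisons (`> 10%`, `> 0 kg loss`) are applied to quantities
  computed directly from the data; tests exercise the boundaries with
  values that are exact in binary floating point.
* Two readings at the same instant cannot order first/last, so such a
  week is not evaluable; ties never need breaking elsewhere because
  events sort on (participant, timestamp).
* Empty inputs flow through every stage: empty streams adjudicate to
  missed/control scenarios, the empty filter returns empty reports, and
  zero-amount results never reach the ledger.
* Malformed, duplicate and unknown-participant records are skipped with
  typed errors (`malformed_record`, `duplicate_record`,
  `unknown_participant`), mirroring how a live trial troubleshoots feeds
  rather than halting on them.

## Problem sizes in the test suite

The acceptance-style tests run the full default cohort — 96 participants
× 24 weeks, roughly 10⁴ diet rows and 10⁴ weigh-ins — through the whole
pipeline; that takes on the order of ten seconds. Unit and property tests
use small constructed fixtures or 12–20-participant cohorts, which keeps
the complete suite comfortably fast while still covering every rule at
its boundary.

## Known limitations

* The engine decides "due for adjudication" from roster status plus an
  explicit `as_of` clock; a live deployment would also want a
  data-transmission activity check, which the trial left undefined.
* The cohort-3 floor is modeled as unconditional; if a trial intends it
  to be contingent on some behavior, configure the floor to zero and fold
  it into the schedule instead.
* File-based ingestion only: vendor APIs, SMS delivery and debit-card
  payment rails are integration concerns outside the engine.
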