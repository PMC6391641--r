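test_that("diet criterion: thresholds, day count, and weekend requirement", {
  crit <- criteria_config()
  # five qualifying days, one a Saturday (enrollment Monday + 5)
  rec <- mk_diet("P001", MONDAY + c(0, 1, 2, 3, 5), rep(1000L, 5))
  expect_true(evaluate_diet_criterion(rec, "female", crit))
  # below the male threshold no day counts, however many are logged
  rec <- mk_diet("P001", MONDAY + c(0, 1, 2, 3, 6), rep(1150L, 5))
  expect_false(evaluate_diet_criterion(rec, "male", crit))
  expect_true(evaluate_diet_criterion(rec, "female", crit))
  # five weekday-only qualifying days: no weekend day, criterion fails
  rec <- mk_diet("P001", MONDAY + 0:4, rep(1400L, 5))
  expect_false(evaluate_diet_criterion(rec, "female", crit))
  expect_true(evaluate_diet_criterion(
    rec, "female", criteria_config(require_weekend_day = FALSE)))
  # a high-calorie weekend day below the count still fails
  rec <- mk_diet("P001", MONDAY + 5:6, rep(3000L, 2))
  expect_false(evaluate_diet_criterion(rec, "female", crit))
})

test_that("exactly 28 of the 128 week-day subsets meet the logging rule", {
  crit <- criteria_config()
  weekdays_of <- weekdays(MONDAY + 0:6)
  n_met <- 0L
  for (mask in 0:127) {
    days <- which(bitwAnd(mask, bitwShiftL(1L, 0:6)) > 0L)
    rec <- mk_diet("P001", MONDAY + (days - 1L), rep(1000L, length(days)))
    got <- evaluate_diet_criterion(rec, "female", crit)
    expect_identical(got, diet_rule_oracle(weekdays_of[days]))
    n_met <- n_met + got
  }
  expect_equal(n_met, 28L)
})

test_that("weight criterion is first-minus-last over retained readings", {
  crit <- criteria_config()
  ev <- mk_weighins("P001", ts_at(MONDAY + c(0, 6)), c(100, 99.5))
  expect_equal(evaluate_weight_criterion(ev, crit),
               list(met = TRUE, delta_kg = 0.5))
  # zero change is not loss
  ev <- mk_weighins("P001", ts_at(MONDAY + c(0, 6)), c(100, 100))
  out <- evaluate_weight_criterion(ev, crit)
  expect_false(out$met)
  expect_equal(out$delta_kg, 0)
  # a single weigh-in is not evaluable
  out <- evaluate_weight_criterion(mk_weighins("P001", ts_at(MONDAY), 100), crit)
  expect_false(out$met)
  expect_true(is.na(out$delta_kg))
  # arrival order never matters: first/last are defined by timestamp
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:7, 1)
    ev <- mk_weighins("P001", ts_at(MONDAY + sort(sample(0:6, n))) +
                        runif(n, 0, 3600), round(runif(n, 90, 101), 1))
    shuffled <- ev[sample(n), ]
    expect_equal(evaluate_weight_criterion(shuffled, crit),
                 evaluate_weight_criterion(ev, crit))
  }
})

test_that("criteria are monotone in the helpful direction", {
  crit <- criteria_config()
  set.seed(13)
  for (rep in 1:30) {
    days <- sort(sample(0:6, sample(0:6, 1)))
    rec <- mk_diet("P001", MONDAY + days, rep(1200L, length(days)))
    before <- evaluate_diet_criterion(rec, "female", crit)
    extra <- setdiff(0:6, days)[1]
    rec2 <- rbind(rec, mk_diet("P001", MONDAY + extra, 1200L))
    # adding a qualifying day never flips met -> unmet
    expect_true(!before || evaluate_diet_criterion(rec2, "female", crit))

    ev <- mk_weighins("P001", ts_at(MONDAY + c(0, 3, 6)),
                      round(runif(3, 95, 105), 1))
    res <- evaluate_weight_criterion(ev, crit)
    ev$weight_kg[3] <- ev$weight_kg[3] - 1  # more loss at the last reading
    expect_true(!res$met || evaluate_weight_criterion(ev, crit)$met)
  }
})

test_that("incentives follow the 2x2 arms, halving, floor and caps", {
  sch <- default_incentive_schedule()
  # control arm earns nothing even with both criteria met
  expect_equal(compute_incentive(4, 1, 10, TRUE, TRUE, sch),
               list(amount_earned = 0L, amount_foregone = 0L))
  # single-component arm: full component on success
  cents <- c(1000L, rep(1200L, 22), 2600L)  # sums to the $300 cap
  sch1000 <- incentive_schedule(
    tibble::tibble(week = 1:24, diet_cents = cents, weight_cents = cents))
  expect_equal(compute_incentive(2, 1, 1, TRUE, NA, sch1000),
               list(amount_earned = 1000L, amount_foregone = 0L))
  # combined arm earns half per singular behavior
  expect_equal(compute_incentive(1, 1, 1, TRUE, FALSE, sch1000),
               list(amount_earned = 500L, amount_foregone = 500L))
  expect_equal(compute_incentive(1, 1, 1, TRUE, TRUE, sch1000)$amount_earned, 1000L)
  # study-total cap truncates the payout
  expect_equal(compute_incentive(2, 1, 24, TRUE, NA, sch1000,
                                 prior_total = 29900L)$amount_earned, 100L)
  # cohort-3 floor is paid even on a missed week, and the weekly cap holds
  missed3 <- compute_incentive(2, 3, 1, FALSE, NA, sch)
  expect_equal(missed3$amount_earned, 200L)
  top3 <- compute_incentive(2, 3, 24, TRUE, NA, sch)
  expect_equal(top3$amount_earned, sch$weekly_cap)
  expect_error(compute_incentive(5, 1, 1, TRUE, TRUE, sch), "unknown group")
})

test_that("earned plus foregone equals the week's attainable maximum", {
  sch <- default_incentive_schedule()
  set.seed(5)
  for (rep in 1:200) {
    g <- sample(1:3, 1); co <- sample(1:3, 1); w <- sample(1:24, 1)
    d <- sample(c(TRUE, FALSE), 1); wt <- sample(c(TRUE, FALSE), 1)
    pay <- compute_incentive(g, co, w, d, wt, sch)
    best <- compute_incentive(g, co, w, TRUE, TRUE, sch)
    expect_equal(pay$amount_earned + pay$amount_foregone,
                 best$amount_earned)
  }
})

test_that("run_week adjudicates exactly the active, due participants", {
  cfg <- study_config()
  roster <- mk_roster(c("P001", "P002", "P003"),
                      group = c(1L, 2L, 3L),
                      status = c("active", "active", "withdrawn"))
  diet <- mk_diet("P002", MONDAY + c(0, 1, 2, 3, 5), rep(1100L, 5))
  weights <- mk_weighins("P001", ts_at(MONDAY + c(0, 6)), c(100, 99))
  res <- run_week(roster, diet, weights, 1, cfg)
  expect_equal(nrow(res), 2)
  expect_false("P003" %in% res$participant_id)
  p1 <- res[res$participant_id == "P001", ]
  expect_true(p1$weight_met)
  expect_false(p1$diet_met)
  expect_equal(p1$scenario, "earned_weight")
  p2 <- res[res$participant_id == "P002", ]
  expect_true(p2$diet_met)
  expect_true(is.na(p2$weight_met))  # not an incented behavior in group 2
  expect_equal(p2$scenario, "earned_diet")

  # empty streams: nothing met, missed/control scenarios
  roster4 <- mk_roster(c("P001", "P004"), group = c(2L, 4L))
  res <- run_week(roster4, diet[0, ], weights[0, ], 1, cfg)
  expect_equal(sort(res$scenario), c("control", "missed"))
  expect_true(all(res$amount_earned_cents[res$scenario == "control"] == 0))

  # unfiltered streams are refused; out-of-range weeks are refused
  raw <- mk_weighins("P001", ts_at(MONDAY), 100, qc_status = "raw")
  expect_error(run_week(roster, diet, raw, 1, cfg), "unfiltered")
  expect_error(run_week(roster, diet, weights, 25, cfg), "outside")

  # due rule: the week must have fully elapsed by as_of
  res <- run_week(roster, diet, weights, 1, cfg, as_of = ts_at(MONDAY + 5))
  expect_equal(nrow(res), 0)
  res <- run_week(roster, diet, weights, 1, cfg, as_of = ts_at(MONDAY + 7))
  expect_equal(nrow(res), 2)
})

test_that("run_week is deterministic under input permutation", {
  cfg <- study_config()
  set.seed(3)
  roster <- mk_roster(sprintf("P%03d", 1:6), group = rep(1:4, length.out = 6))
  diet <- mk_diet(sample(roster$participant_id, 40, replace = TRUE),
                  MONDAY + sample(0:6, 40, replace = TRUE),
                  sample(800:2000, 40))
  weights <- mk_weighins(sample(roster$participant_id, 30, replace = TRUE),
                         ts_at(MONDAY + sample(0:6, 30, replace = TRUE)) +
                           runif(30, 0, 36000),
                         round(runif(30, 85, 110), 1))
  base <- run_week(roster, diet, weights, 1, cfg)
  perm <- run_week(roster[sample(6), ], diet[sample(40), ],
                   weights[sample(30), ], 1, cfg)
  expect_equal(perm, base)
})
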