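stage_one <- function(earned = 1000L, at = ts_at(MONDAY + 7, "17:00:00")) {
  res <- tibble::tibble(participant_id = "P001", week = 1L,
                        diet_met = TRUE, weight_met = NA,
                        weight_delta_kg = NA_real_,
                        amount_earned_cents = as.integer(earned),
                        amount_foregone_cents = 0L, scenario = "earned_diet")
  stage_ledger(res, at = at)
}

test_that("staging creates one computed entry per positive payout", {
  led <- stage_one(1000L)
  expect_equal(nrow(led), 1)
  expect_equal(led$state, "computed")
  expect_equal(led$amount_final_cents, 1000L)

  expect_equal(nrow(stage_one(0L)), 0)

  res <- tibble::tibble(participant_id = "P001", week = 1L,
                        diet_met = TRUE, weight_met = NA,
                        weight_delta_kg = NA_real_,
                        amount_earned_cents = 500L,
                        amount_foregone_cents = 0L, scenario = "earned_diet")
  expect_error(stage_ledger(res, at = ts_at(MONDAY + 7), ledger = led),
               "stage twice")
})

test_that("review transitions: approve, edit with caps, deny; no illegal moves", {
  sch <- default_incentive_schedule()
  at <- ts_at(MONDAY + 7, "18:00:00")
  led <- review_entry(stage_one(), "P001", 1, "approve", at = at, schedule = sch)
  expect_equal(led$state, "approved")
  expect_equal(led$amount_final_cents, 1000L)
  expect_equal(led$reviewed_at, at)

  led <- review_entry(stage_one(), "P001", 1, "edit", new_amount = 500L,
                      at = at, schedule = sch)
  expect_equal(led$state, "edited")
  expect_equal(led$amount_final_cents, 500L)
  expect_equal(led$amount_cents, 1000L)  # computed amount is preserved

  expect_error(review_entry(stage_one(), "P001", 1, "edit", new_amount = 5000L,
                            at = at, schedule = sch), "weekly cap")
  expect_error(review_entry(led, "P001", 1, "approve", at = at, schedule = sch),
               "state 'edited'")
  led <- review_entry(stage_one(), "P001", 1, "deny", at = at, schedule = sch)
  expect_equal(led$state, "denied")
})

test_that("payments schedule at the institutional one-day delay, capped inclusively", {
  sch <- default_incentive_schedule()
  approve_at <- ts_at(MONDAY + 7, "17:00:00")  # Monday 17:00
  led <- review_entry(stage_one(at = approve_at), "P001", 1, "approve",
                      at = approve_at, schedule = sch)
  out <- schedule_payments(led, at = approve_at, schedule = sch)
  expect_equal(out$ledger$state, "scheduled")
  expect_equal(out$ledger$scheduled_at, approve_at + 86400)  # Tuesday 17:00

  # a payment landing exactly on the study cap goes through ...
  mk <- function(weeks, amounts, states) {
    tibble::tibble(participant_id = "P001", week = as.integer(weeks),
                   amount_cents = as.integer(amounts),
                   amount_final_cents = as.integer(amounts), state = states,
                   computed_at = approve_at, reviewed_at = approve_at,
                   scheduled_at = as.POSIXct(ifelse(states == "paid", approve_at, NA),
                                             tz = TZ),
                   paid_at = as.POSIXct(ifelse(states == "paid", approve_at, NA),
                                        tz = TZ))
  }
  led <- mk(1:2, c(28000L, 2000L), c("paid", "approved"))
  out <- schedule_payments(led, at = approve_at, schedule = sch)
  expect_equal(out$ledger$state, c("paid", "scheduled"))
  expect_equal(nrow(out$held), 0)
  # ... but one cent past it is held, not scheduled
  led <- mk(1:2, c(28000L, 2100L), c("paid", "approved"))
  out <- schedule_payments(led, at = approve_at, schedule = sch)
  expect_equal(out$ledger$state, c("paid", "approved"))
  expect_equal(nrow(out$held), 1)
})

test_that("paid entries carry a full monotone timestamp chain", {
  sch <- default_incentive_schedule()
  t0 <- ts_at(MONDAY + 7, "17:00:00")
  led <- stage_one(at = t0)
  led <- review_entry(led, "P001", 1, "approve", at = t0 + 3600, schedule = sch)
  led <- schedule_payments(led, at = t0 + 7200, schedule = sch)$ledger
  led <- mark_paid(led, at = led$scheduled_at[[1]] + 600)
  expect_equal(led$state, "paid")
  with(led, {
    expect_true(computed_at <= reviewed_at)
    expect_true(reviewed_at <= scheduled_at)
    expect_true(scheduled_at <= paid_at)
  })
  expect_error(review_entry(led, "P001", 1, "approve", at = t0, schedule = sch),
               "state 'paid'")
})

test_that("replaying the same action log reconstructs an identical ledger", {
  sch <- default_incentive_schedule()
  t0 <- ts_at(MONDAY + 7, "17:00:00")
  res <- tibble::tibble(participant_id = sprintf("P%03d", 1:4), week = 1L,
                        diet_met = TRUE, weight_met = NA,
                        weight_delta_kg = NA_real_,
                        amount_earned_cents = c(1000L, 500L, 700L, 900L),
                        amount_foregone_cents = 0L, scenario = "earned_diet")
  actions <- tibble::tibble(participant_id = sprintf("P%03d", 1:4),
                            week = 1L,
                            action = c("approve", "edit", "deny", "approve"),
                            new_amount_cents = c(NA, 300L, NA, NA))
  replay <- function() {
    led <- stage_ledger(res, at = t0)
    led <- apply_review_actions(led, actions, at = t0 + 3600, schedule = sch)
    led <- schedule_payments(led, at = t0 + 7200, schedule = sch)$ledger
    mark_paid(led, at = t0 + 7200 + 86400)
  }
  a <- replay(); b <- replay()
  expect_identical(a, b)
  expect_equal(sum(a$amount_final_cents[a$state == "paid"]), 1000L + 300L + 900L)

  # conflicting duplicate actions abort before anything is applied
  dup <- rbind(actions, actions[1, ])
  led <- stage_ledger(res, at = t0)
  expect_error(apply_review_actions(led, dup, at = t0 + 3600, schedule = sch),
               "duplicate")
})
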