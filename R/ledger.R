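#' Payment ledger
#'
#' The trial's payments were human-in-the-loop: the engine computed each
#' week's incentive, study staff reviewed and then approved, edited or
#' denied it, and an institutional approval step delayed the money by
#' about a day after the notification text. The ledger models that
#' lifecycle as a state machine per entry:
#' `computed -> approved | edited | denied`, `approved/edited ->
#' scheduled`, `scheduled -> paid`, with a monotone timestamp chain and
#' cap accounting (scheduled plus paid never exceeds the study total cap).
#' A ledger is a tibble with columns `participant_id`, `week`,
#' `amount_cents`, `amount_final_cents`, `state`, `computed_at`,
#' `reviewed_at`, `scheduled_at`, `paid_at`.
#'
#' @name ledger
NULL

empty_ledger <- function(tz = "America/New_York") {
  na_ts <- as.POSIXct(NA_character_, tz = tz)
  tibble::tibble(participant_id = character(), week = integer(),
                 amount_cents = integer(), amount_final_cents = integer(),
                 state = character(),
                 computed_at = na_ts[0], reviewed_at = na_ts[0],
                 scheduled_at = na_ts[0], paid_at = na_ts[0])
}

#' Stage computed incentives into the ledger
#'
#' One `computed` entry per adjudication result with a positive earned
#' amount; zero-amount results (missed weeks, control arm) produce no
#' entry. Staging the same participant-week twice is a fatal error.
#'
#' @param results Adjudication results from [run_week()].
#' @param at Computation timestamp.
#' @param ledger Existing ledger to append to.
#' @return The ledger with the new `computed` entries.
#' @export
stage_ledger <- function(results, at, ledger = empty_ledger()) {
  pos <- results[results$amount_earned_cents > 0, ]
  if (nrow(pos) == 0) return(ledger)
  key_new <- paste(pos$participant_id, pos$week)
  key_old <- paste(ledger$participant_id, ledger$week)
  if (anyDuplicated(key_new) || any(key_new %in% key_old)) {
    abort("participant-week already staged; refusing to stage twice")
  }
  entries <- tibble::tibble(
    participant_id = pos$participant_id, week = as.integer(pos$week),
    amount_cents = pos$amount_earned_cents,
    amount_final_cents = pos$amount_earned_cents,
    state = "computed",
    computed_at = at, reviewed_at = as.POSIXct(NA_character_, tz = attr(at, "tzone") %||% ""),
    scheduled_at = as.POSIXct(NA_character_, tz = attr(at, "tzone") %||% ""),
    paid_at = as.POSIXct(NA_character_, tz = attr(at, "tzone") %||% ""))
  dplyr::bind_rows(ledger, entries)
}

ledger_row <- function(ledger, participant_id, week) {
  i <- which(ledger$participant_id == participant_id & ledger$week == week)
  if (length(i) != 1L) {
    abort(sprintf("no unique ledger entry for %s week %d", participant_id, week))
  }
  i
}

#' Review one computed entry
#'
#' Staff approve, edit (with a new amount) or deny a computed incentive.
#' Edits must respect the weekly cap and keep the participant's cumulative
#' non-denied total within the study cap. Any transition from a state
#' other than `computed` is an error.
#'
#' @param ledger A ledger tibble.
#' @param participant_id,week Entry key.
#' @param action `"approve"`, `"edit"` or `"deny"`.
#' @param new_amount New amount in cents; required iff `action = "edit"`.
#' @param at Review timestamp.
#' @param schedule The [incentive_schedule()] whose caps apply.
#' @return The updated ledger.
#' @export
review_entry <- function(ledger, participant_id, week, action,
                         new_amount = NULL, at = Sys.time(),
                         schedule = default_incentive_schedule()) {
  i <- ledger_row(ledger, participant_id, week)
  if (ledger$state[[i]] != "computed") {
    abort(sprintf("cannot %s an entry in state '%s'", action, ledger$state[[i]]))
  }
  if (at < ledger$computed_at[[i]]) abort("review timestamp precedes computation")
  if (action == "edit") {
    if (is.null(new_amount) || is.na(new_amount)) abort("edit requires new_amount")
    new_amount <- as.integer(new_amount)
    if (new_amount < 0 || new_amount > schedule$weekly_cap) {
      abort("edited amount violates the weekly cap")
    }
    others <- ledger$participant_id == participant_id &
      seq_len(nrow(ledger)) != i & ledger$state != "denied"
    if (sum(ledger$amount_final_cents[others]) + new_amount > schedule$total_cap) {
      abort("edited amount would exceed the study total cap")
    }
    ledger$amount_final_cents[[i]] <- new_amount
    ledger$state[[i]] <- "edited"
  } else if (action == "approve") {
    ledger$state[[i]] <- "approved"
  } else if (action == "deny") {
    ledger$state[[i]] <- "denied"
  } else {
    abort(sprintf("unknown review action '%s'", action))
  }
  ledger$reviewed_at[[i]] <- at
  ledger
}

#' Apply a file of review actions
#'
#' The staff review UI is replaced by a CSV of actions
#' (`participant_id,week,action,new_amount_cents`). Conflicting duplicate
#' actions for one entry abort before anything is applied.
#'
#' @param ledger A ledger tibble.
#' @param actions Actions tibble or path to the CSV.
#' @param at Review timestamp.
#' @param schedule The governing [incentive_schedule()].
#' @return The updated ledger.
#' @export
apply_review_actions <- function(ledger, actions, at = Sys.time(),
                                 schedule = default_incentive_schedule()) {
  if (is.character(actions)) actions <- read_review_actions(actions)
  if (nrow(actions) == 0) return(ledger)
  if (anyDuplicated(actions[c("participant_id", "week")])) {
    abort("duplicate review actions for one entry; nothing applied")
  }
  for (i in seq_len(nrow(actions))) {
    ledger <- review_entry(ledger, actions$participant_id[[i]],
                           actions$week[[i]], actions$action[[i]],
                           new_amount = actions$new_amount_cents[[i]],
                           at = at, schedule = schedule)
  }
  ledger
}

#' Read a review-actions CSV
#'
#' @param path CSV with header
#'   `participant_id,week,action,new_amount_cents` (new amount blank
#'   except for edits).
#' @return Actions tibble.
#' @export
read_review_actions <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    week = readr::col_integer(),
                    action = readr::col_character(),
                    new_amount_cents = readr::col_integer()))
}

#' Schedule payments for reviewed entries
#'
#' Approved and edited entries are scheduled at `at + delay` — the
#' institutional money-transfer approval took about a day after the
#' notification text. An entry whose amount would push the participant's
#' scheduled-plus-paid total past the study cap is held in its reviewed
#' state and reported, not scheduled.
#'
#' @param ledger A ledger tibble.
#' @param at Scheduling timestamp.
#' @param delay Delay before the money lands (default 24 hours).
#' @param schedule The governing [incentive_schedule()].
#' @return List with `ledger` (updated) and `held` (tibble of entries held
#'   for cap violations, with a reason).
#' @export
schedule_payments <- function(ledger, at, delay = as.difftime(1, units = "days"),
                              schedule = default_incentive_schedule()) {
  held <- ledger[0, ]
  idx <- which(ledger$state %in% c("approved", "edited"))
  # process in key order for determinism
  idx <- idx[order(ledger$participant_id[idx], ledger$week[idx])]
  for (i in idx) {
    if (at < ledger$reviewed_at[[i]]) abort("scheduling timestamp precedes review")
    committed <- ledger$participant_id == ledger$participant_id[[i]] &
      ledger$state %in% c("scheduled", "paid")
    if (sum(ledger$amount_final_cents[committed]) +
        ledger$amount_final_cents[[i]] > schedule$total_cap) {
      held <- dplyr::bind_rows(held, ledger[i, ])
      next
    }
    ledger$state[[i]] <- "scheduled"
    ledger$scheduled_at[[i]] <- at + delay
  }
  list(ledger = ledger, held = held)
}

#' Mark scheduled entries paid
#'
#' @param ledger A ledger tibble.
#' @param at Payment timestamp; must not precede the scheduled time.
#' @return The updated ledger.
#' @export
mark_paid <- function(ledger, at) {
  idx <- which(ledger$state == "scheduled")
  for (i in idx) {
    if (at < ledger$scheduled_at[[i]]) {
      abort("payment timestamp precedes scheduled time")
    }
    ledger$state[[i]] <- "paid"
    ledger$paid_at[[i]] <- at
  }
  ledger
}

#' Export the ledger as CSV
#'
#' @param ledger A ledger tibble.
#' @param path Output CSV.
#' @export
write_ledger <- function(ledger, path) {
  out <- ledger
  for (col in c("computed_at", "reviewed_at", "scheduled_at", "paid_at")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format_iso8601(out[[col]]))
  }
  readr::write_csv(out, path)
  invisible(path)
}
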