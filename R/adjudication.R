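#' Evaluate the weekly dietary self-monitoring criterion
#'
#' A day qualifies when its logged total reaches the sex-specific calorie
#' threshold (default 1000 kcal for women, 1200 for men). The week meets
#' the criterion when at least `min_logging_days` (default 5) days qualify
#' and, when required, at least one qualifying day falls on a Saturday or
#' Sunday.
#'
#' @param week_records Diet records (one row per date) within one
#'   participant-week; columns `date`, `calories_logged`.
#' @param sex `"female"` or `"male"` — selects the calorie threshold.
#' @param criteria A [criteria_config()].
#' @return `TRUE` if the week's logging meets the criterion.
#' @export
evaluate_diet_criterion <- function(week_records, sex,
                                    criteria = criteria_config()) {
  thr <- kcal_threshold(criteria, sex)
  qual <- week_records$date[week_records$calories_logged >= thr]
  if (length(qual) < criteria$min_logging_days) return(FALSE)
  !criteria$require_weekend_day || any(is_weekend(qual))
}

#' Evaluate the weekly weight-loss criterion
#'
#' Weekly weight change is the first retained reading of the week minus
#' the last (by timestamp); the criterion is any amount of weight loss,
#' i.e. a strictly positive change. A week without enough retained
#' readings (see [evaluable_for_weight()]) fails with no change reported.
#'
#' @param week_events QC-filtered weigh-in events within one
#'   participant-week.
#' @param criteria A [criteria_config()].
#' @return List with `met` (logical) and `delta_kg` (first minus last, or
#'   `NA` when the week is not evaluable).
#' @export
evaluate_weight_criterion <- function(week_events,
                                      criteria = criteria_config()) {
  if (!evaluable_for_weight(week_events, criteria)) {
    return(list(met = FALSE, delta_kg = NA_real_))
  }
  kept <- week_events[week_events$qc_status == "retained", ]
  kept <- kept[order(kept$timestamp), ]
  delta <- kept$weight_kg[[1]] - kept$weight_kg[[nrow(kept)]]
  list(met = delta > 0, delta_kg = delta)
}

#' Compute one participant-week's incentive
#'
#' The 2x2 factorial arms map onto the schedule's two components: group 2
#' earns the week's diet component iff the diet criterion is met, group 3
#' earns the weight component iff the weight criterion is met, group 1
#' earns half of each component independently per criterion met (odd cents
#' go to the diet half), and group 4 (control) earns nothing. The cohort
#' weekly floor (default $2 in cohort 3) is added unconditionally for the
#' incentive arms; the weekly total is clamped at the weekly cap so no
#' single week can exceed the printed maximum. Earned amounts are finally
#' truncated so the cumulative total never exceeds the study cap; the
#' foregone amount — what a missed week "would have earned" — is the
#' week's maximum attainable minus the pre-truncation earned amount.
#'
#' @param group Arm 1-4.
#' @param cohort Cohort 1-3 (selects the weekly floor).
#' @param week Study week.
#' @param diet_met,weight_met Criterion outcomes; `NA` (not applicable)
#'   counts as not met.
#' @param schedule An [incentive_schedule()].
#' @param prior_total Cumulative cents already earned before this week.
#' @return List with `amount_earned` and `amount_foregone`, integer cents.
#' @export
compute_incentive <- function(group, cohort, week, diet_met, weight_met,
                              schedule = default_incentive_schedule(),
                              prior_total = 0L) {
  if (!group %in% 1:4) abort(sprintf("unknown group %s", format(group)))
  if (prior_total > schedule$total_cap) abort("prior_total exceeds the study cap")
  if (group == 4L) {
    return(list(amount_earned = 0L, amount_foregone = 0L))
  }
  comp <- schedule_week(schedule, week)
  diet_met <- isTRUE(diet_met)
  weight_met <- isTRUE(weight_met)
  half_diet <- as.integer(ceiling(comp$diet_cents / 2))
  half_weight <- as.integer(floor(comp$weight_cents / 2))
  base <- switch(as.character(group),
    `1` = list(earn = half_diet * diet_met + half_weight * weight_met,
               max = half_diet + half_weight),
    `2` = list(earn = comp$diet_cents * diet_met, max = comp$diet_cents),
    `3` = list(earn = comp$weight_cents * weight_met, max = comp$weight_cents))
  floor_c <- cohort_floor(schedule, cohort)
  earned_pre <- min(base$earn + floor_c, schedule$weekly_cap)
  max_att <- min(base$max + floor_c, schedule$weekly_cap)
  earned <- min(earned_pre, max(0L, schedule$total_cap - as.integer(prior_total)))
  list(amount_earned = as.integer(earned),
       amount_foregone = as.integer(max_att - earned_pre))
}

# Message scenario implied by the arm and criterion outcomes.
scenario_of <- function(group, diet_met, weight_met) {
  if (group == 4L) return("control")
  d <- isTRUE(diet_met); w <- isTRUE(weight_met)
  if (group == 2L) w <- FALSE
  if (group == 3L) d <- FALSE
  if (d && w) "earned_both" else if (d) "earned_diet" else if (w) "earned_weight" else "missed"
}

#' Adjudicate one study week for all active participants
#'
#' For every active rostered participant whose enrollment-anchored week has
#' ended (when `as_of` is given), evaluates the criteria applicable to the
#' participant's arm on that week's records and computes the payout.
#' Withdrawn participants are skipped. Results are deterministic given the
#' inputs and independent of input row order. The weigh-in stream must
#' already be QC-filtered: any event still in `raw` state aborts.
#'
#' @param roster Roster tibble (see [read_roster()]).
#' @param diet_records Normalized diet records (one row per
#'   participant-date).
#' @param weigh_events QC-filtered weigh-in events.
#' @param week Study week to adjudicate.
#' @param config A [study_config()].
#' @param as_of Optional instant; participants whose week has not fully
#'   elapsed by then are not yet due and are skipped.
#' @param prior_totals Optional named vector, participant id to cumulative
#'   cents earned in earlier weeks — enforces the study cap.
#' @return Tibble of adjudication results: one row per adjudicated
#'   participant with criteria outcomes (`NA` where the criterion does not
#'   apply to the arm), the week's weight change, earned and foregone
#'   cents, and the message scenario.
#' @export
run_week <- function(roster, diet_records, weigh_events, week, config,
                     as_of = NULL, prior_totals = NULL) {
  validate_roster(roster)
  if (week < 1L || week > config$n_weeks) {
    abort(sprintf("week %d outside the %d-week study", week, config$n_weeks))
  }
  if (nrow(weigh_events) > 0 && any(weigh_events$qc_status == "raw")) {
    abort("weigh-in stream contains unfiltered (raw) events; run QC first")
  }
  tz <- config$study_timezone
  due <- roster[roster$status == "active", ]
  if (!is.null(as_of)) {
    as_of_date <- if (inherits(as_of, "Date")) as_of else local_date(as_of, tz)
    ends <- due$enrollment_date + 7L * week
    due <- due[ends <= as_of_date, ]
  }
  wday <- if (nrow(weigh_events)) local_date(weigh_events$timestamp, tz) else as.Date(character())
  rows <- lapply(seq_len(nrow(due)), function(i) {
    p <- due[i, ]
    b <- week_date_bounds(p$enrollment_date, week)
    drec <- diet_records[diet_records$participant_id == p$participant_id &
                           diet_records$date >= b$start & diet_records$date < b$end, ]
    wev <- weigh_events[weigh_events$participant_id == p$participant_id &
                          wday >= b$start & wday < b$end, ]
    diet_ok <- evaluate_diet_criterion(drec, p$sex, config$criteria)
    wt <- evaluate_weight_criterion(wev, config$criteria)
    diet_met <- if (p$group %in% c(1L, 2L)) diet_ok else NA
    weight_met <- if (p$group %in% c(1L, 3L)) wt$met else NA
    prior <- if (is.null(prior_totals)) 0L else prior_totals[[p$participant_id]] %||% 0L
    pay <- compute_incentive(p$group, p$cohort, week, diet_met, weight_met,
                             config$schedule, prior)
    tibble::tibble(
      participant_id = p$participant_id, week = as.integer(week),
      diet_met = diet_met, weight_met = weight_met,
      weight_delta_kg = wt$delta_kg,
      amount_earned_cents = pay$amount_earned,
      amount_foregone_cents = pay$amount_foregone,
      scenario = scenario_of(p$group, diet_met, weight_met))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble::tibble(participant_id = character(), week = integer(),
                          diet_met = logical(), weight_met = logical(),
                          weight_delta_kg = numeric(),
                          amount_earned_cents = integer(),
                          amount_foregone_cents = integer(),
                          scenario = character())
  }
  dplyr::arrange(res, .data$participant_id)
}

#' Adjudicate every elapsed week of the study
#'
#' Runs [run_week()] for weeks 1..n (or all weeks due by `as_of`),
#' accumulating each participant's earnings so the study-total cap is
#' enforced across weeks.
#'
#' @inheritParams run_week
#' @param weeks Weeks to adjudicate, default all.
#' @return Combined results tibble, ordered by week then participant.
#' @export
adjudicate_study <- function(roster, diet_records, weigh_events, config,
                             weeks = seq_len(config$n_weeks), as_of = NULL) {
  totals <- setNames(rep(0L, nrow(roster)), roster$participant_id)
  out <- vector("list", length(weeks))
  for (k in seq_along(weeks)) {
    res <- run_week(roster, diet_records, weigh_events, weeks[[k]], config,
                    as_of = as_of, prior_totals = totals)
    if (nrow(res)) {
      totals[res$participant_id] <- totals[res$participant_id] +
        res$amount_earned_cents
    }
    out[[k]] <- res
  }
  dplyr::bind_rows(out)
}

#' Export adjudication results as CSV
#'
#' @param results Results tibble from [run_week()].
#' @param path Output CSV.
#' @export
write_adjudication_results <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}
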