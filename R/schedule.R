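#' Incentive schedule
#'
#' The per-week payout amounts for the two incented behaviors (dietary
#' self-monitoring and weekly weight loss), together with the study-wide
#' constraints: a weekly maximum, a study-total cap, and an unconditional
#' weekly floor by cohort. All money is integer cents so cap arithmetic is
#' exact.
#'
#' The diet and weight columns give the full single-component amount a
#' single-behavior arm can earn that week; the combined arm earns half of
#' each component per criterion met, so its weekly maximum equals the
#' single-component maximum.
#'
#' @param amounts Tibble/data frame with columns `week`, `diet_cents`,
#'   `weight_cents` covering weeks `1..n_weeks`.
#' @param weekly_floor_by_cohort Named integer vector of cents added
#'   unconditionally each week to incentive-arm participants, by cohort
#'   (names "1", "2", "3").
#' @param total_cap Study-total cap in cents.
#' @param weekly_cap Single-week maximum in cents (applied after the floor).
#' @return An `incentive_schedule` object.
#' @export
incentive_schedule <- function(amounts,
                               weekly_floor_by_cohort = c("1" = 0L, "2" = 0L, "3" = 200L),
                               total_cap = 30000L,
                               weekly_cap = 2800L) {
  amounts <- tibble::as_tibble(amounts)
  stopifnot(all(c("week", "diet_cents", "weight_cents") %in% names(amounts)))
  amounts$week <- as.integer(amounts$week)
  amounts$diet_cents <- as.integer(amounts$diet_cents)
  amounts$weight_cents <- as.integer(amounts$weight_cents)
  sched <- structure(
    list(amounts = amounts[order(amounts$week), ],
         weekly_floor_by_cohort = vapply(weekly_floor_by_cohort, as.integer, integer(1)),
         total_cap = as.integer(total_cap),
         weekly_cap = as.integer(weekly_cap)),
    class = "incentive_schedule")
  validate_incentive_schedule(sched)
  sched
}

validate_incentive_schedule <- function(s) {
  a <- s$amounts
  if (!identical(a$week, seq_len(nrow(a)))) {
    abort("schedule must cover weeks 1..n_weeks exactly once each")
  }
  if (any(a$diet_cents < 0) || any(a$weight_cents < 0) ||
      any(s$weekly_floor_by_cohort < 0)) {
    abort("all schedule amounts must be nonnegative")
  }
  # weekly attainable total for any arm/cohort never exceeds the weekly cap:
  # single-component arms attain the component amount, the combined arm the
  # sum of the two halves; the floor is clamped at payout time.
  weekly_max <- pmax(a$diet_cents, a$weight_cents,
                     ceiling(a$diet_cents / 2) + floor(a$weight_cents / 2))
  if (any(weekly_max > s$weekly_cap)) {
    abort("a weekly attainable total exceeds weekly_cap")
  }
  if (sum(pmax(a$diet_cents, a$weight_cents)) != s$total_cap) {
    abort("weekly single-component maxima must sum exactly to total_cap")
  }
  invisible(s)
}

#' Default 24-week escalating schedule
#'
#' The printed envelope fixes only the corners: at most $28 in any single
#' week, at most $300 over the study, and a $2 weekly floor in cohort 3.
#' This default fills the envelope with a nondecreasing ramp (in dollars:
#' 5,5,5,5, 8,8,8,8, 10,10,10,10, 12,12,12,12, 17,17,17,17, 20,20, 24, 28)
#' that sums exactly to $300 with a single-week maximum of $28. Any
#' schedule satisfying the envelope invariants is accepted in its place.
#'
#' @param n_weeks Number of study weeks; only the default 24 has a shipped
#'   ramp, other lengths must supply their own amounts via
#'   [incentive_schedule()].
#' @return An `incentive_schedule`.
#' @export
default_incentive_schedule <- function(n_weeks = 24L) {
  if (n_weeks != 24L) {
    abort("the shipped ramp covers 24 weeks; build other lengths with incentive_schedule()")
  }
  dollars <- c(rep(5, 4), rep(8, 4), rep(10, 4), rep(12, 4), rep(17, 4),
               rep(20, 2), 24, 28)
  cents <- as.integer(dollars * 100)
  incentive_schedule(tibble::tibble(week = seq_len(24L),
                                    diet_cents = cents,
                                    weight_cents = cents))
}

#' @export
print.incentive_schedule <- function(x, ...) {
  cat(sprintf("<incentive_schedule> %d weeks, total cap %s, weekly cap %s\n",
              nrow(x$amounts), format_cents(x$total_cap), format_cents(x$weekly_cap)))
  cat(sprintf("  weekly floor by cohort: %s\n",
              paste(sprintf("%s=%s", names(x$weekly_floor_by_cohort),
                            format_cents(x$weekly_floor_by_cohort)), collapse = ", ")))
  invisible(x)
}

# Component amounts for one week.
schedule_week <- function(schedule, week) {
  a <- schedule$amounts
  if (week < 1L || week > nrow(a)) abort(sprintf("week %d outside schedule", week))
  as.list(a[a$week == week, c("diet_cents", "weight_cents")])
}

cohort_floor <- function(schedule, cohort) {
  f <- schedule$weekly_floor_by_cohort[[as.character(cohort)]]
  if (is.null(f)) 0L else f
}
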