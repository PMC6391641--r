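#' Messaging configuration
#'
#' Weekly outcome texts are written once, up front, for every scenario a
#' participant can face, and every rendering must fit a single SMS
#' (160 characters) — oversized renderings are a configuration error,
#' never silently truncated. Earned messages state the amount added to the
#' participant's debit card; missed messages are loss-framed, stating the
#' amount the participant *would have earned*. Templates use `{behavior}`
#' and `{amount}` placeholders.
#'
#' @param max_length Maximum rendered body length in characters.
#' @param templates Named list of templates for kinds `earned`, `missed`,
#'   `control`, `reminder`.
#' @param behavior_phrases Named list with `earned` phrases by scenario and
#'   `missed` phrases by group ("1", "2", "3").
#' @param tip_library Ordered character vector of encouragement /
#'   skill-building tips, cycled deterministically.
#' @param tips_per_week Tip messages per week for cohorts 2-3.
#' @return A `messaging_config` list.
#' @export
messaging_config <- function(
    max_length = 160L,
    templates = list(
      earned = "Great job on {behavior} this week! {amount} will be added to your debit card. Keep up the good work!",
      missed = "You did not {behavior} this week. If you had, you would have earned {amount}.",
      control = "Keep it up! Remember to weigh yourself and log your meals in your diet app this week.",
      reminder = "Reminder: your in-person group session is on {date}. See you there!"),
    behavior_phrases = list(
      earned = c(earned_both = "logging your food and losing weight",
                 earned_diet = "logging your food",
                 earned_weight = "losing weight"),
      missed = c("1" = "log your food or lose enough weight",
                 "2" = "log your food",
                 "3" = "lose enough weight")),
    tip_library = default_tip_library(),
    tips_per_week = 2L) {
  cfg <- structure(list(max_length = as.integer(max_length),
                        templates = templates,
                        behavior_phrases = behavior_phrases,
                        tip_library = as.character(tip_library),
                        tips_per_week = as.integer(tips_per_week)),
                   class = "messaging_config")
  validate_messaging_config(cfg)
  cfg
}

validate_messaging_config <- function(cfg) {
  stopifnot(length(cfg$tip_library) >= 1, cfg$tips_per_week >= 0)
  # worst case: longest behavior phrase with a 6-character dollar amount
  probe_amount <- "$88.88"
  worst <- c(
    render_template(cfg$templates$earned,
                    behavior = cfg$behavior_phrases$earned[[which.max(nchar(cfg$behavior_phrases$earned))]],
                    amount = probe_amount),
    render_template(cfg$templates$missed,
                    behavior = cfg$behavior_phrases$missed[[which.max(nchar(cfg$behavior_phrases$missed))]],
                    amount = probe_amount),
    cfg$templates$control,
    render_template(cfg$templates$reminder, date = "September 30"),
    cfg$tip_library)
  too_long <- nchar(worst) > cfg$max_length
  if (any(too_long)) {
    abort(sprintf("template rendering exceeds %d characters: %s",
                  cfg$max_length, worst[too_long][[1]]))
  }
  no_dollar <- c(cfg$templates$control, cfg$templates$reminder, cfg$tip_library)
  if (any(grepl("$", no_dollar, fixed = TRUE))) {
    abort("only earned/missed templates may mention a dollar amount")
  }
  invisible(cfg)
}

default_tip_library <- function() {
  c("Tip: plan tomorrow's meals tonight - logging is easier when you know what's coming.",
    "Tip: weigh in first thing in the morning for the most consistent readings.",
    "Tip: log as you eat - waiting until evening makes meals easy to forget.",
    "Tip: keep your scale on a hard, flat floor for accurate readings.",
    "You're building a habit - every day you log counts, even the rough ones.",
    "Tip: pre-log your usual breakfast to start each day with a win.",
    "Small steps add up. A short walk after dinner is a great place to start.",
    "Tip: restaurant meal? Estimate high - honest logs beat pretty ones.",
    "Keep going! Consistency beats perfection, in logging and in weighing.",
    "Tip: set a daily phone alarm for your weigh-in and your evening log check.")
}

render_template <- function(template, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    template <- gsub(paste0("{", nm, "}"), vals[[nm]], template, fixed = TRUE)
  }
  template
}

new_outbox <- function() {
  tibble::tibble(participant_id = character(), send_on = as.Date(character()),
                 kind = character(), body = character())
}

#' Compose the weekly outcome message for one adjudication result
#'
#' Earned scenarios congratulate the participant on the behavior(s) met
#' and state the earned amount; missed scenarios are loss-framed, naming
#' the behavior the arm incents and the foregone amount; the control arm
#' receives an encouragement message with no dollar amount. Whole-dollar
#' amounts render without cents ("$10"), fractional ones with
#' ("$10.50").
#'
#' @param result One row of a [run_week()] result.
#' @param group The participant's arm (1-4) — selects the missed-behavior
#'   phrase.
#' @param config A [messaging_config()].
#' @param send_on Date the message goes out.
#' @return One-row outbox tibble (`participant_id`, `send_on`, `kind`,
#'   `body`).
#' @export
compose_weekly_message <- function(result, group,
                                   config = messaging_config(),
                                   send_on = NULL) {
  scenario <- result$scenario
  body <- switch(scenario,
    control = config$templates$control,
    missed = render_template(
      config$templates$missed,
      behavior = config$behavior_phrases$missed[[as.character(group)]],
      amount = format_cents(result$amount_foregone_cents)),
    earned_both = ,
    earned_diet = ,
    earned_weight = render_template(
      config$templates$earned,
      behavior = config$behavior_phrases$earned[[scenario]],
      amount = format_cents(result$amount_earned_cents)),
    abort(sprintf("unknown scenario '%s'", scenario)))
  if (nchar(body) > config$max_length) {
    abort(sprintf("rendered message is %d characters (max %d): %s",
                  nchar(body), config$max_length, body))
  }
  kind <- switch(scenario, control = "control_encouragement",
                 missed = "incentive_missed", "incentive_earned")
  tibble::tibble(participant_id = result$participant_id,
                 send_on = send_on %||% as.Date(NA),
                 kind = kind, body = body)
}

#' Schedule the week's encouragement / skill-tip messages
#'
#' Cohorts 2 and 3 receive `tips_per_week` (default 2) extra messages per
#' week, cycled deterministically through the tip library so reruns are
#' reproducible; cohort 1 receives none.
#'
#' @param participant One roster row (needs `participant_id`, `cohort`,
#'   `enrollment_date`).
#' @param week Study week.
#' @param config A [messaging_config()].
#' @return Outbox tibble, possibly empty.
#' @export
schedule_tips <- function(participant, week, config = messaging_config()) {
  if (!participant$cohort %in% c(2L, 3L) || config$tips_per_week == 0L) {
    return(new_outbox())
  }
  k <- seq_len(config$tips_per_week)
  idx <- (as.integer(week) - 1L) * config$tips_per_week + k
  n <- length(config$tip_library)
  body <- config$tip_library[((idx - 1L) %% n) + 1L]
  # spread through the week (days 3 and 6 of the 7-day window for 2/week)
  offsets <- round(seq(2, 5, length.out = config$tips_per_week))
  tibble::tibble(participant_id = participant$participant_id,
                 send_on = participant$enrollment_date + 7L * (week - 1L) + offsets,
                 kind = "tip", body = body)
}

#' Schedule an in-person session reminder
#'
#' Every participant, in every arm, receives the same reminder for each
#' group session; a session dated before the participant's enrollment
#' produces no message.
#'
#' @param participant One roster row.
#' @param session_date Date of the in-person session.
#' @param config A [messaging_config()].
#' @return Outbox tibble with one row, or empty.
#' @export
schedule_session_reminder <- function(participant, session_date,
                                      config = messaging_config()) {
  if (session_date < participant$enrollment_date) return(new_outbox())
  body <- render_template(config$templates$reminder,
                          date = format(session_date, "%B %d"))
  tibble::tibble(participant_id = participant$participant_id,
                 send_on = session_date - 1L,
                 kind = "session_reminder", body = body)
}

#' Biweekly session dates over the study
#'
#' In-person group sessions run every 2 weeks over the study (12 sessions
#' in 24 weeks), starting in week 1.
#'
#' @param study_start First session date.
#' @param n_weeks Study length in weeks.
#' @return Vector of session dates.
#' @export
biweekly_session_dates <- function(study_start, n_weeks = 24L) {
  study_start + 14L * seq.int(0L, length.out = n_weeks %/% 2L)
}

#' Write an outbox file
#'
#' @param outbox Outbox tibble.
#' @param path Output CSV.
#' @export
write_outbox <- function(outbox, path) {
  readr::write_csv(outbox, path)
  invisible(path)
}
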