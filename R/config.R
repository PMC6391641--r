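#' Weekly criteria configuration
#'
#' Thresholds for the two adjudicated behaviors. Defaults are the trial's
#' printed rules: log at least 1200 kcal (men) / 1000 kcal (women) on 5 or
#' more days per week including one weekend day; weigh in at least twice a
#' week; and a 10% same-day relative weight spread above which a day's
#' readings are discarded as possible gaming.
#'
#' @param kcal_threshold_female,kcal_threshold_male Minimum daily logged
#'   calories for a day to count, by sex (kcal).
#' @param min_logging_days Minimum qualifying days per week.
#' @param require_weekend_day Must one qualifying day fall on Saturday or
#'   Sunday?
#' @param min_weighins_per_week Retained weigh-ins needed for the week's
#'   weight change to be evaluable.
#' @param same_day_gaming_fraction Same-day relative spread (max-min)/min
#'   strictly above which all of that day's weigh-ins are removed.
#' @return A `criteria_config` list.
#' @export
criteria_config <- function(kcal_threshold_female = 1000L,
                            kcal_threshold_male = 1200L,
                            min_logging_days = 5L,
                            require_weekend_day = TRUE,
                            min_weighins_per_week = 2L,
                            same_day_gaming_fraction = 0.10) {
  stopifnot(kcal_threshold_female > 0, kcal_threshold_male > 0,
            min_logging_days >= 1, min_logging_days <= 7,
            min_weighins_per_week >= 1,
            same_day_gaming_fraction > 0, same_day_gaming_fraction < 1)
  structure(list(
    kcal_threshold_female = as.integer(kcal_threshold_female),
    kcal_threshold_male = as.integer(kcal_threshold_male),
    min_logging_days = as.integer(min_logging_days),
    require_weekend_day = isTRUE(require_weekend_day),
    min_weighins_per_week = as.integer(min_weighins_per_week),
    same_day_gaming_fraction = same_day_gaming_fraction
  ), class = "criteria_config")
}

kcal_threshold <- function(criteria, sex) {
  switch(sex,
         female = criteria$kcal_threshold_female,
         male = criteria$kcal_threshold_male,
         abort(sprintf("unknown sex '%s'", sex)))
}

#' Study configuration
#'
#' Bundles everything the weekly pipeline needs: study length, cohort
#' sizes, adjudication criteria, the incentive schedule, messaging
#' templates, and the study timezone in which calendar days and weeks are
#' cut. Weeks are enrollment-anchored per participant: week w covers the
#' half-open interval [enrollment + 7(w-1) days, enrollment + 7w days).
#'
#' @param n_weeks Study length in weeks.
#' @param cohort_sizes Enrollment per sequential cohort.
#' @param criteria A [criteria_config()].
#' @param schedule An [incentive_schedule()].
#' @param messaging A [messaging_config()].
#' @param study_timezone IANA zone in which days/weeks are defined.
#' @return A `study_config` list.
#' @export
study_config <- function(n_weeks = 24L,
                         cohort_sizes = c(34L, 31L, 31L),
                         criteria = criteria_config(),
                         schedule = default_incentive_schedule(n_weeks),
                         messaging = messaging_config(),
                         study_timezone = "America/New_York") {
  stopifnot(n_weeks >= 1, all(cohort_sizes >= 1),
            inherits(criteria, "criteria_config"),
            inherits(schedule, "incentive_schedule"),
            inherits(messaging, "messaging_config"))
  if (nrow(schedule$amounts) != n_weeks) {
    abort("schedule length must equal n_weeks")
  }
  if (!study_timezone %in% OlsonNames()) {
    abort(sprintf("'%s' is not a known timezone", study_timezone))
  }
  structure(list(n_weeks = as.integer(n_weeks),
                 cohort_sizes = as.integer(cohort_sizes),
                 criteria = criteria,
                 schedule = schedule,
                 messaging = messaging,
                 study_timezone = study_timezone),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d weeks, cohorts n=%s, tz %s\n",
              x$n_weeks, paste(x$cohort_sizes, collapse = "/"), x$study_timezone))
  invisible(x)
}

#' Read a study configuration from YAML
#'
#' The document mirrors [study_config()]; any omitted field keeps its
#' default. The schedule may be given as a list of weekly dollar (or cent)
#' amounts, or omitted to use the shipped 24-week ramp.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  doc <- yaml::read_yaml(path)
  crit <- do.call(criteria_config, doc$criteria %||% list())
  n_weeks <- as.integer(doc$n_weeks %||% 24L)
  sched <- if (is.null(doc$schedule)) {
    default_incentive_schedule(n_weeks)
  } else {
    s <- doc$schedule
    amounts <- tibble::tibble(
      week = seq_along(s$weekly_cents),
      diet_cents = as.integer(s$weekly_cents),
      weight_cents = as.integer(s$weekly_cents))
    incentive_schedule(
      amounts,
      weekly_floor_by_cohort = unlist(s$weekly_floor_by_cohort %||%
                                        list("1" = 0L, "2" = 0L, "3" = 200L)),
      total_cap = s$total_cap %||% 30000L,
      weekly_cap = s$weekly_cap %||% 2800L)
  }
  msg_args <- doc$messaging %||% list()
  study_config(n_weeks = n_weeks,
               cohort_sizes = as.integer(doc$cohort_sizes %||% c(34L, 31L, 31L)),
               criteria = crit,
               schedule = sched,
               messaging = do.call(messaging_config, msg_args),
               study_timezone = doc$study_timezone %||% "America/New_York")
}
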