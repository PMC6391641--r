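#' Same-day anti-gaming weight filter
#'
#' Home cellular scales can be gamed: someone else steps on, or the
#' participant keeps partial weight off the scale. Readings taken by
#' different people on the same day are discordant, so for each
#' participant-local calendar day the filter computes the relative spread
#' `(max - min) / min` over that day's weights and, when the spread is
#' strictly greater than the threshold (default 10%), removes *all* of the
#' day's readings — with two or more discordant readings there is no way to
#' attribute any one of them to the participant. Days at or below the
#' threshold are retained in full. The filter is idempotent: re-running it
#' on retained events removes nothing.
#'
#' @param events Weigh-in tibble for a single participant (columns
#'   `participant_id`, `timestamp`, `weight_kg`, `qc_status`).
#' @param threshold Relative spread above which a day is removed; in
#'   `(0, 1)`.
#' @param tz Study timezone defining calendar-day boundaries.
#' @return A list with `events` (input rows with `qc_status` set to
#'   `"retained"` or `"removed"`) and `reports` (one row per removed day:
#'   `participant_id`, `date`, `n_removed`, `max_relative_spread`).
#' @export
filter_same_day_weights <- function(events, threshold = 0.10,
                                    tz = "America/New_York") {
  stopifnot(threshold > 0, threshold < 1)
  empty_reports <- tibble::tibble(participant_id = character(),
                                  date = as.Date(character()),
                                  n_removed = integer(),
                                  max_relative_spread = numeric())
  if (nrow(events) == 0) {
    return(list(events = events, reports = empty_reports))
  }
  if (length(unique(events$participant_id)) > 1L) {
    abort("filter_same_day_weights expects events for a single participant")
  }
  day <- local_date(events$timestamp, tz)
  spread_by_day <- tapply(events$weight_kg, day,
                          function(w) (max(w) - min(w)) / min(w))
  day_chr <- as.character(day)
  spread <- as.numeric(spread_by_day[day_chr])
  removed <- spread > threshold
  events$qc_status <- ifelse(removed, "removed", "retained")
  bad_days <- names(spread_by_day)[spread_by_day > threshold]
  reports <- if (length(bad_days)) {
    tibble::tibble(
      participant_id = events$participant_id[[1]],
      date = as.Date(bad_days),
      n_removed = vapply(bad_days, function(d) sum(day_chr == d), integer(1)),
      max_relative_spread = as.numeric(spread_by_day[bad_days]))
  } else empty_reports
  list(events = events, reports = reports)
}

# Apply the same-day filter across a whole multi-participant stream.
qc_filter_stream <- function(events, threshold = 0.10, tz = "America/New_York") {
  if (nrow(events) == 0) {
    return(filter_same_day_weights(events, threshold, tz))
  }
  parts <- split(events, events$participant_id)
  out <- lapply(parts, filter_same_day_weights, threshold = threshold, tz = tz)
  list(events = dplyr::bind_rows(lapply(out, `[[`, "events")),
       reports = dplyr::bind_rows(lapply(out, `[[`, "reports")))
}

#' Is a participant-week evaluable for weight loss?
#'
#' Weekly weight change is first-minus-last over the week, which needs at
#' least `min_weighins_per_week` retained readings (default 2) at two or
#' more distinct times. Evaluability is judged on the retained set only:
#' a week whose readings were all removed by QC is not evaluable.
#'
#' @param week_events Retained weigh-in events within one participant-week.
#' @param criteria A [criteria_config()].
#' @return `TRUE` if the week's weight change can be computed.
#' @export
evaluable_for_weight <- function(week_events, criteria = criteria_config()) {
  kept <- week_events[week_events$qc_status == "retained", ]
  nrow(kept) >= criteria$min_weighins_per_week &&
    length(unique(kept$timestamp)) >= 2L
}

#' Export QC reports as CSV
#'
#' @param reports QC report tibble from [filter_same_day_weights()].
#' @param path Output CSV.
#' @export
write_qc_reports <- function(reports, path) {
  readr::write_csv(reports, path)
  invisible(path)
}
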