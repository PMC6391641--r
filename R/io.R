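#' Event-stream and roster input/output
#'
#' The engine consumes three flat files: a weigh-in stream
#' (`participant_id,timestamp,weight_kg`, ISO-8601 timestamps with UTC
#' offset), a diet stream (`participant_id,date,calories`) and a
#' participant roster
#' (`participant_id,sex,cohort,group,enrollment_date,status,scale_id`).
#' Streams are line-delimited comma records, with or without the exact
#' header line. Ingestion mirrors the trial's tolerate-and-troubleshoot
#' posture: malformed lines, duplicates and unknown participants are
#' reported as typed errors and skipped, never fatal; only an unreadable
#' file aborts.
#'
#' @name stream_io
NULL

read_delim_lines <- function(path, header) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(trimws(lines[[1]]), header)) lines <- lines[-1]
  lines
}

roster_ids <- function(roster) {
  if (is.null(roster)) NULL else roster$participant_id
}

#' Read a weigh-in stream
#'
#' @param path File of `participant_id,timestamp,weight_kg` records.
#' @param tz Study timezone used to interpret and re-express timestamps.
#' @param roster Optional roster tibble; records for unknown participants
#'   are dropped with an `unknown_participant` error each.
#' @return A list with `events` (tibble: participant_id, timestamp,
#'   weight_kg, qc_status = "raw", sorted by participant then time) and
#'   `errors` (tibble: code, detail).
#' @export
read_weighin_stream <- function(path, tz = "America/New_York", roster = NULL) {
  lines <- read_delim_lines(path, "participant_id,timestamp,weight_kg")
  errors <- new_ingest_errors()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    if (length(f) != 3L) {
      errors <- rbind(errors, ingest_error("malformed_record",
        sprintf("line %d: expected 3 fields, got %d", i, length(f))))
      next
    }
    ts <- parse_iso8601(f[[2]], tz)
    wt <- suppressWarnings(as.numeric(f[[3]]))
    if (is.na(ts) || is.na(wt) || !nzchar(f[[1]])) {
      errors <- rbind(errors, ingest_error("malformed_record",
        sprintf("line %d: unparseable record '%s'", i, lines[[i]])))
      next
    }
    if (wt <= 0) {
      errors <- rbind(errors, ingest_error("malformed_record",
        sprintf("line %d: nonpositive weight %g", i, wt)))
      next
    }
    rows[[i]] <- tibble::tibble(participant_id = f[[1]], timestamp = ts,
                                weight_kg = wt)
  }
  events <- dplyr::bind_rows(rows)
  if (nrow(events) == 0) {
    events <- tibble::tibble(participant_id = character(),
                             timestamp = as.POSIXct(character(), tz = tz),
                             weight_kg = numeric())
  }
  dup <- duplicated(events[c("participant_id", "timestamp", "weight_kg")])
  if (any(dup)) {
    for (j in which(dup)) {
      errors <- rbind(errors, ingest_error("duplicate_record",
        sprintf("%s @ %s weight %g repeated", events$participant_id[[j]],
                format_iso8601(events$timestamp[[j]]), events$weight_kg[[j]])))
    }
    events <- events[!dup, ]
  }
  known <- roster_ids(roster)
  if (!is.null(known)) {
    bad <- !(events$participant_id %in% known)
    for (id in events$participant_id[bad]) {
      errors <- rbind(errors, ingest_error("unknown_participant",
        sprintf("weigh-in for unenrolled id '%s'", id)))
    }
    events <- events[!bad, ]
  }
  events <- events[order(events$participant_id, events$timestamp), ]
  events$qc_status <- rep("raw", nrow(events))
  list(events = tibble::as_tibble(events), errors = errors)
}

#' Read a diet-log stream
#'
#' Logging apps emit one row per food entry; the weekly criterion concerns
#' daily totals, so multiple rows for the same participant-date are summed
#' into one record.
#'
#' @inheritParams read_weighin_stream
#' @return A list with `records` (tibble: participant_id, date,
#'   calories_logged; one row per participant-date) and `errors`.
#' @export
read_diet_stream <- function(path, roster = NULL) {
  lines <- read_delim_lines(path, "participant_id,date,calories")
  errors <- new_ingest_errors()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    d <- if (length(f) == 3L) suppressWarnings(as.Date(f[[2]], format = "%Y-%m-%d")) else NA
    kcal <- if (length(f) == 3L) suppressWarnings(as.numeric(f[[3]])) else NA
    if (length(f) != 3L || is.na(d) || is.na(kcal) || kcal < 0 ||
        kcal != round(kcal) || !nzchar(f[[1]])) {
      errors <- rbind(errors, ingest_error("malformed_record",
        sprintf("line %d: unparseable record '%s'", i, lines[[i]])))
      next
    }
    rows[[i]] <- tibble::tibble(participant_id = f[[1]], date = d,
                                calories_logged = as.integer(kcal))
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) == 0) {
    records <- tibble::tibble(participant_id = character(),
                              date = as.Date(character()),
                              calories_logged = integer())
  }
  known <- roster_ids(roster)
  if (!is.null(known)) {
    bad <- !(records$participant_id %in% known)
    for (id in unique(records$participant_id[bad])) {
      errors <- rbind(errors, ingest_error("unknown_participant",
        sprintf("diet record for unenrolled id '%s'", id)))
    }
    records <- records[!bad, ]
  }
  records <- records |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(calories_logged = as.integer(sum(.data$calories_logged)),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id, .data$date)
  list(records = records, errors = errors)
}

#' Read a participant roster
#'
#' @param path CSV with header `participant_id,sex,cohort,group,
#'   enrollment_date,status,scale_id`.
#' @return Roster tibble with typed columns.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  r <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         sex = readr::col_character(),
                         cohort = readr::col_integer(),
                         group = readr::col_integer(),
                         enrollment_date = readr::col_date(),
                         status = readr::col_character(),
                         scale_id = readr::col_character()))
  validate_roster(r)
  r
}

validate_roster <- function(roster) {
  need <- c("participant_id", "sex", "cohort", "group", "enrollment_date",
            "status", "scale_id")
  if (!all(need %in% names(roster))) abort("roster is missing required columns")
  if (anyDuplicated(roster$participant_id)) abort("duplicate participant ids in roster")
  if (!all(roster$sex %in% c("female", "male"))) abort("sex must be female/male")
  if (!all(roster$cohort %in% 1:3)) abort("cohort must be 1-3")
  if (!all(roster$group %in% 1:4)) abort("group must be 1-4")
  if (!all(roster$status %in% c("active", "withdrawn", "completed"))) {
    abort("status must be active/withdrawn/completed")
  }
  invisible(roster)
}

#' Write event streams and rosters
#'
#' Writers emit exactly the formats the readers accept, so a write/read
#' round trip reproduces every field.
#'
#' @param events,records,roster Tibbles as produced by the readers or the
#'   simulator.
#' @param path Output file.
#' @export
write_weighin_stream <- function(events, path) {
  lines <- c("participant_id,timestamp,weight_kg",
             sprintf("%s,%s,%s", events$participant_id,
                     format_iso8601(events$timestamp),
                     formatC(events$weight_kg, format = "fg", digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_weighin_stream
#' @export
write_diet_stream <- function(records, path) {
  lines <- c("participant_id,date,calories",
             sprintf("%s,%s,%d", records$participant_id,
                     format(records$date, "%Y-%m-%d"), records$calories_logged))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_weighin_stream
#' @export
write_roster <- function(roster, path) {
  readr::write_csv(roster, path)
  invisible(path)
}

#' Enrollment-anchored study week of an instant
#'
#' Week w covers the half-open interval
#' [enrollment + 7(w-1) days, enrollment + 7w days) in the study timezone.
#'
#' @param enrollment_date Participant's enrollment date (`Date`).
#' @param instant A `POSIXct` instant or a `Date`.
#' @param n_weeks Study length.
#' @param tz Study timezone.
#' @return Integer week in `1..n_weeks`, or `NA` if the instant precedes
#'   enrollment or falls past week `n_weeks`.
#' @export
study_week_of <- function(enrollment_date, instant, n_weeks = 24L,
                          tz = "America/New_York") {
  day <- if (inherits(instant, "Date")) instant else local_date(instant, tz)
  w <- as.integer(floor(as.numeric(day - enrollment_date) / 7)) + 1L
  w[w < 1L | w > n_weeks] <- NA_integer_
  w
}

# Date bounds [start, end) of a participant's week, as study-local dates.
week_date_bounds <- function(enrollment_date, week) {
  list(start = enrollment_date + 7L * (week - 1L),
       end = enrollment_date + 7L * week)
}
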