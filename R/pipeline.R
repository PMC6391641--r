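#' Weekly batch pipeline
#'
#' Thin orchestration over the engine: `cmd_simulate` writes a synthetic
#' dataset, `cmd_adjudicate` runs QC, adjudication, messaging and ledger
#' staging for one week or for all due weeks, and `cmd_ledger` applies a
#' staff review-actions file and schedules payments. Every run writes a
#' manifest (timestamp, config and input digests, counts, ingest errors
#' by code) so reruns are auditable; the clock is always an explicit
#' `as_of`, never the wall clock, so identical inputs give byte-identical
#' outputs.
#'
#' @name pipeline
NULL

file_digest <- function(path) unname(tools::md5sum(path))

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config), collapse = "\n"), tmp)
  file_digest(tmp)
}

write_manifest <- function(dir, name, config, inputs, counts, errors) {
  err_counts <- if (nrow(errors)) as.list(table(errors$code)) else list()
  manifest <- list(
    command = name,
    config_digest = config_digest(config),
    input_digests = as.list(vapply(inputs, file_digest, character(1))),
    counts = counts,
    errors_by_code = err_counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname pipeline
#' @param out_dir Output directory for the dataset.
#' @param sim A [simulation_config()].
#' @param study A [study_config()].
#' @param seed Optional seed overriding `sim$seed`.
#' @return `cmd_simulate`: the dataset list, invisibly.
#' @export
cmd_simulate <- function(out_dir, sim = simulation_config(),
                         study = study_config(), seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  dataset <- generate_cohort(sim, study)
  write_dataset(dataset, out_dir)
  write_manifest(out_dir, "simulate", list(sim = sim, study = study),
                 inputs = file.path(out_dir, c("roster.csv", "weighins.csv", "diet.csv")),
                 counts = list(participants = nrow(dataset$roster),
                               weighin_events = nrow(dataset$weighins),
                               diet_records = nrow(dataset$diet)),
                 errors = new_ingest_errors())
  invisible(dataset)
}

#' @rdname pipeline
#' @param data_dir Directory holding `roster.csv`, `weighins.csv`,
#'   `diet.csv`; outputs are written alongside.
#' @param week Integer week, or `"all-due"` for every week that has fully
#'   elapsed by `as_of`.
#' @param as_of The run's clock (POSIXct or Date).
#' @return `cmd_adjudicate`: list with `results`, `outbox`, `ledger`,
#'   `qc_reports`, `errors`, invisibly.
#' @export
cmd_adjudicate <- function(data_dir, week = "all-due", as_of,
                           study = study_config()) {
  tz <- study$study_timezone
  roster_path <- file.path(data_dir, "roster.csv")
  weigh_path <- file.path(data_dir, "weighins.csv")
  diet_path <- file.path(data_dir, "diet.csv")
  roster <- read_roster(roster_path)
  win <- read_weighin_stream(weigh_path, tz = tz, roster = roster)
  din <- read_diet_stream(diet_path, roster = roster)
  errors <- rbind(win$errors, din$errors)
  qc <- qc_filter_stream(win$events, study$criteria$same_day_gaming_fraction, tz)

  weeks <- if (identical(week, "all-due")) {
    seq_len(study$n_weeks)
  } else {
    as.integer(week)
  }
  results <- adjudicate_study(roster, din$records, qc$events, study,
                              weeks = weeks, as_of = as_of)

  as_of_ts <- if (inherits(as_of, "Date")) {
    as.POSIXct(paste(as_of, "17:00:00"), tz = tz)
  } else as_of
  roster_by_id <- roster[match(results$participant_id, roster$participant_id), ]
  outbox <- new_outbox()
  if (nrow(results)) {
    msgs <- lapply(seq_len(nrow(results)), function(i) {
      p <- roster_by_id[i, ]
      send_on <- p$enrollment_date + 7L * results$week[[i]]
      rbind(compose_weekly_message(results[i, ], p$group, study$messaging,
                                   send_on = send_on),
            schedule_tips(p, results$week[[i]], study$messaging))
    })
    outbox <- dplyr::bind_rows(msgs)
    outbox <- dplyr::arrange(outbox, .data$send_on, .data$participant_id, .data$kind)
  }
  ledger <- stage_ledger(results, at = as_of_ts)

  write_adjudication_results(results, file.path(data_dir, "results.csv"))
  write_outbox(outbox, file.path(data_dir, "outbox.csv"))
  write_ledger(ledger, file.path(data_dir, "ledger.csv"))
  write_qc_reports(qc$reports, file.path(data_dir, "qc_reports.csv"))
  write_manifest(data_dir, "adjudicate", study,
                 inputs = c(roster_path, weigh_path, diet_path),
                 counts = list(participants_due = length(unique(results$participant_id)),
                               adjudicated = nrow(results),
                               messages = nrow(outbox),
                               ledger_entries = nrow(ledger)),
                 errors = errors)
  invisible(list(results = results, outbox = outbox, ledger = ledger,
                 qc_reports = qc$reports, errors = errors))
}

#' Read back an exported ledger CSV
#'
#' @param path Ledger CSV written by [write_ledger()].
#' @param tz Study timezone.
#' @return Ledger tibble.
#' @export
read_ledger <- function(path, tz = "America/New_York") {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           week = readr::col_integer(),
                           amount_cents = readr::col_integer(),
                           amount_final_cents = readr::col_integer(),
                           state = readr::col_character(),
                           .default = readr::col_character()))
  for (col in c("computed_at", "reviewed_at", "scheduled_at", "paid_at")) {
    raw[[col]] <- parse_iso8601(raw[[col]], tz)
  }
  raw
}

#' @rdname pipeline
#' @param actions_file Review-actions CSV
#'   (`participant_id,week,action,new_amount_cents`).
#' @param delay Payment delay after review approval.
#' @return `cmd_ledger`: list with `ledger` and `held`, invisibly.
#' @export
cmd_ledger <- function(data_dir, actions_file, as_of,
                       study = study_config(),
                       delay = as.difftime(1, units = "days")) {
  tz <- study$study_timezone
  as_of_ts <- if (inherits(as_of, "Date")) {
    as.POSIXct(paste(as_of, "17:00:00"), tz = tz)
  } else as_of
  ledger <- read_ledger(file.path(data_dir, "ledger.csv"), tz)
  ledger <- apply_review_actions(ledger, actions_file, at = as_of_ts,
                                 schedule = study$schedule)
  sp <- schedule_payments(ledger, at = as_of_ts, delay = delay,
                          schedule = study$schedule)
  write_ledger(sp$ledger, file.path(data_dir, "ledger.csv"))
  if (nrow(sp$held)) {
    write_ledger(sp$held, file.path(data_dir, "ledger_held.csv"))
  }
  invisible(list(ledger = sp$ledger, held = sp$held))
}
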