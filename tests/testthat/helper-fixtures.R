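TZ <- "America/New_York"

ts_at <- function(date, time = "07:00:00") {
  as.POSIXct(paste(date, time), tz = TZ)
}

# weigh-in tibble from parallel vectors; qc_status defaults to retained so
# criterion-level tests can skip the QC pass
mk_weighins <- function(id, timestamps, weights, qc_status = "retained") {
  tibble::tibble(participant_id = id, timestamp = timestamps,
                 weight_kg = weights, qc_status = qc_status)
}

mk_diet <- function(id, dates, kcal) {
  tibble::tibble(participant_id = id, date = as.Date(dates),
                 calories_logged = as.integer(kcal))
}

mk_roster <- function(ids, group = 2L, cohort = 1L, sex = "female",
                      enrollment = as.Date("2016-03-07"), status = "active") {
  n <- length(ids)
  tibble::tibble(participant_id = ids,
                 sex = rep_len(sex, n), cohort = as.integer(rep_len(cohort, n)),
                 group = as.integer(rep_len(group, n)),
                 enrollment_date = rep_len(enrollment, n),
                 status = rep_len(status, n),
                 scale_id = sprintf("BT%05d", seq_len(n)))
}

# Monday 2016-03-07 anchors enrollment so weekday arithmetic is readable:
# enrollment + 0 is Monday, + 5 Saturday, + 6 Sunday.
MONDAY <- as.Date("2016-03-07")

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent restatement of the weekly logging rule used as an oracle:
# >= min_days qualifying days of which at least one is Sat/Sun
diet_rule_oracle <- function(qualifying_weekdays, min_days = 5) {
  length(qualifying_weekdays) >= min_days &&
    any(qualifying_weekdays %in% c("Saturday", "Sunday"))
}
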