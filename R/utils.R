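#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# Format integer cents the way the weekly texts print dollars: whole-dollar
# amounts without ".00" ("$28"), fractional amounts with cents ("$27.50").
format_cents <- function(cents) {
  stopifnot(is.numeric(cents), all(cents >= 0), all(cents == round(cents)))
  whole <- cents %% 100L == 0L
  out <- character(length(cents))
  out[whole] <- sprintf("$%d", cents[whole] %/% 100L)
  out[!whole] <- sprintf("$%.2f", cents[!whole] / 100)
  out
}

# ISO-8601 with numeric UTC offset, second resolution; the on-disk timestamp
# format for weigh-in streams.
format_iso8601 <- function(ts) {
  format(ts, "%Y-%m-%dT%H:%M:%S%z")
}

parse_iso8601 <- function(x, tz) {
  # %z consumes offsets like -0500; result is re-expressed in the study zone
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  # fall back to offset-less local time
  missing <- is.na(out) & !is.na(x)
  if (any(missing)) {
    out[missing] <- as.POSIXct(x[missing], format = "%Y-%m-%dT%H:%M:%S", tz = tz)
  }
  out
}

# Calendar date of an instant in the study timezone (participant-local day).
local_date <- function(ts, tz) {
  as.Date(format(ts, "%Y-%m-%d", tz = tz))
}

is_weekend <- function(date) {
  format(date, "%u") %in% c("6", "7")
}

new_ingest_errors <- function(code = character(), detail = character()) {
  tibble::tibble(code = code, detail = detail)
}

ingest_error <- function(code, detail) {
  codes <- c("no_data", "connection_error", "duplicate_record",
             "malformed_record", "unknown_participant")
  stopifnot(code %in% codes)
  new_ingest_errors(code, detail)
}
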