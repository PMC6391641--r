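#' Simulation configuration
#'
#' Defines a synthetic cohort with the behavioral structure the engine
#' assumes: per-participant adherence propensities (Beta-distributed daily
#' logging and weighing probabilities, with an optional linear logit drift
#' to mimic declining participation), lognormal-free Gaussian daily
#' calorie totals, a drifting noisy weight trajectory that loses weight
#' only in diet-adherent weeks, occasional injected same-day gaming
#' weigh-ins that the QC filter should catch, and weekly dropout.
#'
#' `p_log_day` / `p_weigh_day` are either `c(shape1, shape2)` of a Beta
#' distribution or a single fixed probability (handy for forcing full
#' adherence).
#'
#' @param seed Integer seed; a fixed seed reproduces the dataset
#'   byte-for-byte.
#' @param cohort_sizes Participants per sequential cohort.
#' @param p_log_day Daily calorie-logging propensity (Beta shapes or fixed).
#' @param kcal_when_logging `c(mean, sd)` of a logged day's calorie total.
#' @param p_weigh_day Daily weigh-in propensity (Beta shapes or fixed).
#' @param true_loss_rate kg lost per diet-adherent week.
#' @param weight_noise_sd Measurement noise SD in kg.
#' @param baseline_weight `c(mean, sd)` of starting weight in kg.
#' @param gaming_rate Per-day probability that a weigh-in day also gets a
#'   discordant proxy weigh-in.
#' @param dropout_hazard Per-week withdrawal probability.
#' @param adherence_drift Additive weekly drift on the logit of both daily
#'   propensities (negative = declining engagement).
#' @param p_female Probability a participant is female.
#' @param study_start First cohort's first enrollment date.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 20160307L,
                              cohort_sizes = c(34L, 31L, 31L),
                              p_log_day = c(6, 2),
                              kcal_when_logging = c(1400, 250),
                              p_weigh_day = c(5, 3),
                              true_loss_rate = 0.25,
                              weight_noise_sd = 0.4,
                              baseline_weight = c(105, 15),
                              gaming_rate = 0.01,
                              dropout_hazard = 0.01,
                              adherence_drift = -0.02,
                              p_female = 0.7,
                              study_start = as.Date("2016-03-07")) {
  stopifnot(gaming_rate >= 0, gaming_rate <= 1,
            dropout_hazard >= 0, dropout_hazard <= 1,
            weight_noise_sd >= 0, kcal_when_logging[[2]] >= 0,
            baseline_weight[[2]] >= 0, true_loss_rate >= 0,
            p_female >= 0, p_female <= 1)
  structure(list(seed = as.integer(seed), cohort_sizes = as.integer(cohort_sizes),
                 p_log_day = p_log_day, kcal_when_logging = kcal_when_logging,
                 p_weigh_day = p_weigh_day, true_loss_rate = true_loss_rate,
                 weight_noise_sd = weight_noise_sd,
                 baseline_weight = baseline_weight,
                 gaming_rate = gaming_rate, dropout_hazard = dropout_hazard,
                 adherence_drift = adherence_drift, p_female = p_female,
                 study_start = study_start),
            class = "simulation_config")
}

# draw a propensity: fixed value, or Beta(shape1, shape2)
draw_propensity <- function(shape, n) {
  if (length(shape) == 1L) rep(as.numeric(shape), n)
  else stats::rbeta(n, shape[[1]], shape[[2]])
}

# run code with the RNG seeded locally, restoring global RNG state after
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Inject a same-day gaming weigh-in
#'
#' Adds one discordant reading to a day that already has a genuine
#' weigh-in: the added weight is the day's minimum times a factor drawn
#' uniformly from (1 + threshold, 1.5), so the day's relative spread is
#' guaranteed to exceed the QC threshold and the filter must fire.
#'
#' @param day_events Weigh-in events of one participant-day (>= 1 row).
#' @param threshold The QC same-day spread threshold.
#' @return `day_events` plus one injected row.
#' @export
inject_gaming_event <- function(day_events, threshold = 0.10) {
  stopifnot(nrow(day_events) >= 1)
  factor <- runif(1, 1 + threshold + 1e-6, 1.5)
  fake <- day_events[which.min(day_events$weight_kg), ]
  fake$weight_kg <- round(min(day_events$weight_kg) * factor, 2)
  fake$timestamp <- fake$timestamp + round(runif(1, 3600, 6 * 3600))
  dplyr::bind_rows(day_events, fake)
}

#' Generate a synthetic study cohort with ground truth
#'
#' Produces a roster, raw weigh-in and diet streams in the engine's file
#' formats, and a per-participant-week ground-truth table computed during
#' generation by literally applying the criteria definitions to the
#' generated data (with the QC rule applied to the weigh-ins). Group
#' assignment is blocked randomization within cohort; cohorts enroll
#' sequentially. With the default configuration the roster holds 96
#' participants in cohorts of 34/31/31.
#'
#' @param sim A [simulation_config()].
#' @param study A [study_config()].
#' @return List with `roster`, `weighins` (raw events), `diet`
#'   (per-entry rows), and `ground_truth` (tibble: participant_id, week,
#'   diet_met, weight_met, n_gaming_days).
#' @export
generate_cohort <- function(sim = simulation_config(), study = study_config()) {
  with_local_seed(sim$seed, {
    tz <- study$study_timezone
    n <- sum(sim$cohort_sizes)
    ids <- sprintf("P%03d", seq_len(n))
    cohort <- rep(seq_along(sim$cohort_sizes), sim$cohort_sizes)
    # blocked randomization to the 4 arms within each cohort
    group <- unlist(lapply(sim$cohort_sizes, function(m) {
      blocks <- unlist(lapply(seq_len(ceiling(m / 4)), function(b) sample(1:4)))
      blocks[seq_len(m)]
    }), use.names = FALSE)
    sex <- ifelse(runif(n) < sim$p_female, "female", "male")
    # cohorts enroll sequentially, ~26 weeks apart, with a 2-week window
    enrollment <- sim$study_start + (cohort - 1L) * 182L +
      sample(0:13, n, replace = TRUE)
    p_log <- draw_propensity(sim$p_log_day, n)
    p_weigh <- draw_propensity(sim$p_weigh_day, n)
    baseline <- pmax(60, rnorm(n, sim$baseline_weight[[1]], sim$baseline_weight[[2]]))
    # geometric weekly dropout; participants active through week w-1 withdraw
    # at the start of week w
    dropout_week <- if (sim$dropout_hazard > 0) {
      1L + stats::rgeom(n, sim$dropout_hazard)
    } else rep(Inf, n)

    roster <- tibble::tibble(
      participant_id = ids, sex = sex, cohort = as.integer(cohort),
      group = as.integer(group), enrollment_date = enrollment,
      status = ifelse(dropout_week <= study$n_weeks, "withdrawn", "active"),
      scale_id = sprintf("BT%05d", sample(10000:99999, n)))

    thr <- study$criteria$same_day_gaming_fraction
    diet_rows <- list(); weigh_rows <- list(); truth_rows <- list()
    for (i in seq_len(n)) {
      weight_now <- baseline[[i]]
      last_week <- min(study$n_weeks, dropout_week[[i]] - 1L)
      if (last_week < 1L) next
      for (w in seq_len(last_week)) {
        drift <- sim$adherence_drift * (w - 1L)
        pl <- stats::plogis(stats::qlogis(pmin(pmax(p_log[[i]], 1e-9), 1 - 1e-9)) + drift)
        pw <- stats::plogis(stats::qlogis(pmin(pmax(p_weigh[[i]], 1e-9), 1 - 1e-9)) + drift)
        if (length(sim$p_log_day) == 1L) pl <- sim$p_log_day
        if (length(sim$p_weigh_day) == 1L) pw <- sim$p_weigh_day
        dates <- enrollment[[i]] + 7L * (w - 1L) + 0:6
        logged <- runif(7) < pl
        kcal <- integer(0)
        if (any(logged)) {
          kcal <- pmax(0, round(rnorm(sum(logged), sim$kcal_when_logging[[1]],
                                      sim$kcal_when_logging[[2]])))
        }
        drec <- tibble::tibble(participant_id = ids[[i]],
                               date = dates[logged],
                               calories_logged = as.integer(kcal))
        diet_met <- evaluate_diet_criterion(drec, sex[[i]], study$criteria)
        # weight drifts down only through diet-adherent weeks
        daily_loss <- if (diet_met) sim$true_loss_rate / 7 else 0
        weighed <- runif(7) < pw
        wev <- NULL
        gaming_days <- 0L
        if (any(weighed)) {
          day_idx <- which(weighed)
          true_wt <- weight_now - daily_loss * (day_idx - 0.5)
          meas <- round(true_wt + rnorm(length(day_idx), 0, sim$weight_noise_sd), 2)
          ts <- as.POSIXct(paste(dates[day_idx], "06:45:00"), tz = tz) +
            round(runif(length(day_idx), 0, 7200))
          wev <- tibble::tibble(participant_id = ids[[i]], timestamp = ts,
                                weight_kg = meas, qc_status = "raw")
          gamed <- runif(length(day_idx)) < sim$gaming_rate
          if (any(gamed)) {
            parts <- split(wev, seq_len(nrow(wev)))
            for (j in which(gamed)) {
              parts[[j]] <- inject_gaming_event(parts[[j]], thr)
            }
            wev <- dplyr::bind_rows(parts)
            gaming_days <- sum(gamed)
          }
        }
        weight_now <- weight_now - daily_loss * 7
        # ground truth: literal re-application of the criteria (QC included)
        wk_met <- if (is.null(wev)) FALSE else {
          filtered <- filter_same_day_weights(wev, thr, tz)$events
          evaluate_weight_criterion(filtered, study$criteria)$met
        }
        diet_rows[[length(diet_rows) + 1L]] <- drec
        if (!is.null(wev)) weigh_rows[[length(weigh_rows) + 1L]] <- wev
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          participant_id = ids[[i]], week = w, diet_met = diet_met,
          weight_met = wk_met, n_gaming_days = gaming_days)
      }
    }
    diet <- dplyr::bind_rows(diet_rows)
    weighins <- dplyr::bind_rows(weigh_rows)
    if (nrow(weighins)) {
      weighins <- weighins[order(weighins$participant_id, weighins$timestamp), ]
    }
    if (nrow(diet)) diet <- diet[order(diet$participant_id, diet$date), ]
    list(roster = roster, weighins = weighins, diet = diet,
         ground_truth = dplyr::bind_rows(truth_rows))
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits exactly the flat files the ingestion layer consumes
#' (`roster.csv`, `weighins.csv`, `diet.csv`) plus the ground-truth table
#' (`ground_truth.csv`) for test oracles.
#'
#' @param dataset List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(dataset$roster, file.path(dir, "roster.csv"))
  write_weighin_stream(dataset$weighins, file.path(dir, "weighins.csv"))
  write_diet_stream(dataset$diet, file.path(dir, "diet.csv"))
  readr::write_csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
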