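#' Medication-day generation settings
#'
#' Controls the stochastic generation of synthetic medication days: waking
#' day length, number of doses, admissible dose sizes and the minimum gap
#' between doses. Defaults emulate typical oral levodopa therapy: waking
#' days of 14-18 h, 3-7 doses per day, sizes on a 5 mg lattice up to
#' 400 mg, the first dose at wake, and at least 90 minutes between doses.
#'
#' @param wake_length_range `(min, max)` waking day length in minutes.
#' @param dose_count_range `(min, max)` doses per day.
#' @param dose_size_choices admissible dose sizes (mg).
#' @param min_interdose_gap minimum gap between doses (minutes); must be at
#'   least one grid step.
#' @param grid_step sampling step (minutes).
#' @param first_dose_at_wake place the first dose at `t = 0`.
#' @return An object of class `day_gen_config`.
#' @export
day_gen_config <- function(wake_length_range = c(840, 1080),
                           dose_count_range = c(3, 7),
                           dose_size_choices = seq(5, 400, by = 5),
                           min_interdose_gap = 90,
                           grid_step = 10,
                           first_dose_at_wake = TRUE) {
  stopifnot(length(wake_length_range) == 2,
            wake_length_range[1] <= wake_length_range[2],
            length(dose_count_range) == 2,
            dose_count_range[1] <= dose_count_range[2],
            length(dose_size_choices) >= 1)
  if (min_interdose_gap < grid_step)
    stop("min_interdose_gap must be at least one grid step")
  structure(list(wake_length_range = wake_length_range,
                 dose_count_range = dose_count_range,
                 dose_size_choices = dose_size_choices,
                 min_interdose_gap = min_interdose_gap,
                 grid_step = grid_step,
                 first_dose_at_wake = first_dose_at_wake),
            class = "day_gen_config")
}

#' Generate one synthetic medication day
#'
#' Draws a waking day length (uniform on the grid inside the configured
#' range), a dose count, grid-aligned intake times with all gaps at least
#' `min_interdose_gap`, and dose sizes uniform over the configured
#' choices; then simulates the TRS trace from the endogenous steady state
#' at wake. For a 16-hour day on a 10-minute grid the trace holds the
#' initial state plus 95 further grid states.
#'
#' @param params a [patient_params()].
#' @param cfg a [day_gen_config()].
#' @param seed optional integer seed.
#' @return A list with elements `schedule` ([dose_schedule()]) and
#'   `trace` ([state_trace()]).
#' @export
generate_day <- function(params, cfg = day_gen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gs <- cfg$grid_step
  lengths <- seq(ceiling(cfg$wake_length_range[1] / gs) * gs,
                 floor(cfg$wake_length_range[2] / gs) * gs, by = gs)
  day_length <- if (length(lengths) == 1) lengths else sample(lengths, 1)
  n <- if (cfg$dose_count_range[1] == cfg$dose_count_range[2])
    cfg$dose_count_range[1]
  else sample(seq(cfg$dose_count_range[1], cfg$dose_count_range[2]), 1)
  if (n == 0) {
    schedule <- dose_schedule()
  } else {
    gap_steps <- ceiling(cfg$min_interdose_gap / gs)
    last_slot <- day_length / gs - 1      # last grid index usable for a dose
    if ((n - 1) * gap_steps > last_slot)
      stop("infeasible dose count for day length and minimum gap")
    # sequential draw of grid slots with gaps >= gap_steps
    slots <- integer(n)
    slots[1] <- if (cfg$first_dose_at_wake) 0L else
      sample(0:(last_slot - (n - 1) * gap_steps), 1)
    if (n > 1) {
      for (j in 2:n) {
        lo <- slots[j - 1] + gap_steps
        hi <- last_slot - (n - j) * gap_steps
        slots[j] <- if (lo == hi) lo else sample(lo:hi, 1)
      }
    }
    sizes <- sample(cfg$dose_size_choices, n, replace = TRUE)
    schedule <- dose_schedule(slots * gs, sizes)
  }
  trace <- simulate_trace(params, schedule, day_length, grid_step = gs)
  list(schedule = schedule, trace = trace)
}

#' Generate a full synthetic cohort
#'
#' Samples `n_patients` virtual patients from the population and generates
#' `n_days` medication days for each; the default 50 x 3 layout yields 150
#' day records.
#'
#' @param pop a [population_model()].
#' @param n_patients number of patients (default 50).
#' @param n_days days per patient (default 3).
#' @param cfg a [day_gen_config()].
#' @param seed integer seed controlling both sampling and day generation.
#' @return A list with `patients` (list of `patient_params`) and `days`
#'   (list of records `patient_id`, `day_id`, `schedule`, `trace`).
#' @export
generate_cohort <- function(pop = default_population(), n_patients = 50,
                            n_days = 3, cfg = day_gen_config(),
                            seed = 1) {
  patients <- sample_patients(pop, n_patients, seed = seed)
  days <- list()
  for (i in seq_len(n_patients)) {
    for (d in seq_len(n_days)) {
      day <- generate_day(patients[[i]], cfg,
                          seed = seed + 7919L * i + 104729L * d)
      days[[length(days) + 1]] <- list(patient_id = i, day_id = d,
                                       schedule = day$schedule,
                                       trace = day$trace)
    }
  }
  list(patients = patients, days = days)
}

#' Write / read a medication-day dataset (long CSV)
#'
#' One row per grid point with columns `patient_id`, `day_id`, `time_min`,
#' `trs`, `dose_mg` (`dose_mg` is 0 at grid points without a dose). The
#' round trip through disk is lossless for grid-aligned schedules.
#'
#' @param days list of day records as produced by [generate_cohort()].
#' @param path CSV file path.
#' @export
write_dataset <- function(days, path) {
  rows <- lapply(days, function(rec) {
    tr <- rec$trace
    dose <- numeric(length(tr$times))
    if (length(rec$schedule$times)) {
      idx <- match(rec$schedule$times, tr$times)
      if (anyNA(idx)) stop("dose times must lie on the trace grid")
      dose[idx] <- dose[idx] + rec$schedule$sizes
    }
    data.frame(patient_id = rec$patient_id, day_id = rec$day_id,
               time_min = tr$times, trs = tr$values, dose_mg = dose)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = integer(0), day_id = integer(0),
               time_min = numeric(0), trs = numeric(0), dose_mg = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop(sprintf(
                   "malformed dataset CSV '%s': %s", path, conditionMessage(e))))
  need <- c("patient_id", "day_id", "time_min", "trs", "dose_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed dataset CSV '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop(sprintf("malformed dataset CSV '%s': incomplete row %d",
                 path, bad[1] + 1L))
  days <- list()
  for (pid in unique(df$patient_id)) {
    for (did in unique(df$day_id[df$patient_id == pid])) {
      sub <- df[df$patient_id == pid & df$day_id == did, ]
      sub <- sub[order(sub$time_min), ]
      has_dose <- sub$dose_mg > 0
      days[[length(days) + 1]] <- list(
        patient_id = pid, day_id = did,
        schedule = dose_schedule(sub$time_min[has_dose],
                                 sub$dose_mg[has_dose]),
        trace = state_trace(sub$time_min, sub$trs))
    }
  }
  days
}
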