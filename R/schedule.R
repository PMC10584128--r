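#' Daily medication schedule
#'
#' A set of oral dose events for one day: intake times in minutes from wake
#' and integer dose sizes in mg. Internally times are stored absolute; the
#' optimization layer works with the equivalent (first time, inter-dose
#' intervals) representation.
#'
#' @param times numeric vector of intake times (minutes from wake,
#'   non-decreasing, non-negative).
#' @param sizes numeric vector of dose sizes (mg, non-negative).
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(times = numeric(0), sizes = numeric(0)) {
  if (length(times) != length(sizes))
    stop("times and sizes must have equal length")
  if (length(times)) {
    o <- order(times)
    times <- as.numeric(times[o]); sizes <- as.numeric(sizes[o])
    if (any(times < 0)) stop("dose times must be non-negative")
    if (any(sizes < 0)) stop("dose sizes must be non-negative")
  }
  structure(list(times = times, sizes = sizes), class = "dose_schedule")
}

#' Build a schedule from first-dose time and intervals
#'
#' @param t1 time of the first dose (minutes from wake).
#' @param intervals time intervals between consecutive doses (minutes).
#' @param sizes dose sizes (mg), length `length(intervals) + 1`.
#' @export
schedule_from_intervals <- function(t1, intervals, sizes) {
  dose_schedule(cumsum(c(t1, intervals)), sizes)
}

#' Total number of doses in a schedule
#' @param schedule a `dose_schedule`.
#' @export
n_doses <- function(schedule) length(schedule$times)

#' @export
print.dose_schedule <- function(x, ...) {
  if (!length(x$times)) {
    cat("Empty dose schedule\n")
  } else {
    cat("Dose schedule:\n")
    print(data.frame(time_min = x$times, dose_mg = x$sizes))
  }
  invisible(x)
}

#' Align dose times to the sampling grid
#'
#' Rounds each intake time to the nearest grid point (a dose taken at 8:17
#' on a 10-minute grid is treated as taken at 8:20).
#'
#' @param schedule a `dose_schedule`.
#' @param grid_step grid step in minutes.
#' @export
align_schedule <- function(schedule, grid_step = 10) {
  dose_schedule(round(schedule$times / grid_step) * grid_step,
                schedule$sizes)
}

#' TRS state trace over one day
#'
#' A 10-minute-gridded (by default) time series of TRS scores for one
#' patient day. The grid runs `t = 0, step, ..., day_length - step`; the
#' value at `t = 0` is the initial (wake) state.
#'
#' @param times strictly increasing grid with a constant step (minutes).
#' @param values TRS scores, one per grid point.
#' @param day_length minutes awake; defaults to `max(times) + step`.
#' @return An object of class `state_trace`.
#' @export
state_trace <- function(times, values, day_length = NULL) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1) {
    steps <- diff(times)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-8)
      stop("trace grid must be strictly increasing with a constant step")
  }
  step <- if (length(times) > 1) times[2] - times[1] else NA_real_
  if (is.null(day_length))
    day_length <- if (is.na(step)) max(times, 0) else max(times) + step
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 day_length = as.numeric(day_length)),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("TRS state trace: %d points, step %g min, day length %g min\n",
              length(x$times),
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA,
              x$day_length))
  cat(sprintf("  range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

trace_step <- function(trace) {
  if (length(trace$times) < 2) stop("trace needs at least two points")
  trace$times[2] - trace$times[1]
}
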