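#' Constraint set for schedule optimization
#'
#' The four optional constraints on the decision variables:
#' 1. intake times take discrete values on a lattice (`time_step`);
#' 2. the first dose is taken at wake (`t1 = 0`);
#' 3. only two dose sizes, a morning dose and equal maintenance doses;
#' 4. equal time intervals between doses.
#' The decision vector always holds the time block first and the dose
#' block second; with all four constraints active it reduces to
#' `[dt, d_mor, d_main]` for any number of doses.
#'
#' @param c1_discrete_times,c2_first_at_wake,c3_two_dose_sizes,c4_equal_intervals
#'   logical flags.
#' @param time_step lattice for discrete intake times (minutes).
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(c1_discrete_times = FALSE,
                           c2_first_at_wake = FALSE,
                           c3_two_dose_sizes = FALSE,
                           c4_equal_intervals = FALSE,
                           time_step = 10) {
  structure(list(c1 = isTRUE(c1_discrete_times),
                 c2 = isTRUE(c2_first_at_wake),
                 c3 = isTRUE(c3_two_dose_sizes),
                 c4 = isTRUE(c4_equal_intervals),
                 time_step = time_step),
            class = "constraint_set")
}

#' @rdname constraint_set
#' @param which integer vector naming the active constraints, e.g.
#'   `c(1, 2)` or `1:4`.
#' @export
constraints_from_numbers <- function(which, time_step = 10) {
  constraint_set(1 %in% which, 2 %in% which, 3 %in% which, 4 %in% which,
                 time_step = time_step)
}

# number of decision variables for n doses under a constraint set
encoding_dim <- function(constraints, n) {
  n_time <- (if (constraints$c4) 1L else n - 1L) +
    (if (constraints$c2) 0L else 1L)
  n_dose <- if (constraints$c3) 2L else n
  n_time + n_dose
}

#' Encode / decode a schedule as a decision vector
#'
#' Maps between a [dose_schedule()] and the constraint-dependent decision
#' vector (times block first, dose block second): without constraints a
#' 4-dose schedule encodes to the 8 variables
#' `[t1, dt2, dt3, dt4, d1, d2, d3, d4]`; with all four constraints it
#' encodes to `[dt, d_mor, d_main]`. `decode(encode(s)) = s` whenever the
#' schedule satisfies the active constraints.
#'
#' @param schedule a [dose_schedule()].
#' @param constraints a [constraint_set()].
#' @export
encode_schedule <- function(schedule, constraints) {
  n <- n_doses(schedule)
  if (n < 1) stop("cannot encode an empty schedule")
  t1 <- schedule$times[1]
  intervals <- diff(schedule$times)
  if (constraints$c2 && abs(t1) > 1e-9)
    stop("constraint 2 requires the first dose at wake (t1 = 0)")
  tb <- numeric(0)
  if (!constraints$c2) tb <- t1
  if (constraints$c4) {
    if (n > 2 && diff(range(intervals)) > 1e-9)
      stop("constraint 4 requires equal intervals")
    tb <- c(tb, if (n > 1) intervals[1] else numeric(0))
    if (n == 1) tb <- c(tb, 0)  # degenerate single-dose placeholder
  } else {
    tb <- c(tb, intervals)
  }
  if (constraints$c3) {
    if (n > 2 && diff(range(schedule$sizes[-1])) > 1e-9)
      stop("constraint 3 requires equal maintenance doses")
    db <- c(schedule$sizes[1], if (n > 1) schedule$sizes[2] else 0)
  } else {
    db <- schedule$sizes
  }
  c(tb, db)
}

#' @rdname encode_schedule
#' @param vec decision vector.
#' @param n number of doses the vector describes.
#' @param day_length optional day length used only for validation.
#' @export
decode_schedule <- function(vec, constraints, n, day_length = NULL) {
  if (length(vec) != encoding_dim(constraints, n))
    stop(sprintf("decision vector has length %d but the constraint set implies %d",
                 length(vec), encoding_dim(constraints, n)))
  i <- 1
  t1 <- if (constraints$c2) 0 else { v <- vec[i]; i <- i + 1; v }
  intervals <- if (constraints$c4) {
    dt <- vec[i]; i <- i + 1
    rep(dt, n - 1)
  } else {
    v <- vec[seq(i, length.out = n - 1)]; i <- i + n - 1
    v
  }
  sizes <- if (constraints$c3) {
    d <- vec[i:(i + 1)]
    c(d[1], rep(d[2], n - 1))
  } else {
    vec[seq(i, length.out = n)]
  }
  sch <- schedule_from_intervals(t1, intervals, sizes)
  if (!is.null(day_length) && length(sch$times) &&
      max(sch$times) > day_length)
    stop("decoded schedule extends beyond the day length")
  sch
}
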