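#' Target specification for schedule optimization
#'
#' The optimal state `theta`, the target range `[theta_min, theta_max]`
#' and the threshold `theta_t` that the state should not fall below after
#' the first dose, all in TRS units.
#'
#' @param theta optimal state.
#' @param theta_min,theta_max target range bounds.
#' @param theta_t threshold state.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(theta, theta_min, theta_max, theta_t) {
  if (!(theta_min <= theta && theta <= theta_max))
    stop("theta must lie inside [theta_min, theta_max]")
  if (theta_t > theta_min) stop("theta_t must not exceed theta_min")
  structure(list(theta = theta, theta_min = theta_min,
                 theta_max = theta_max, theta_t = theta_t),
            class = "target_spec")
}

#' Patient-specific target from the 10/20-40% rule
#'
#' The threshold is 10% of the patient's maximum state `BASE + EMAX` and
#' the target range spans 20% to 40% of that maximum; the optimal state is
#' the midpoint of the range.
#'
#' @param params a [patient_params()].
#' @export
target_from_patient <- function(params) {
  mx <- params$BASE + params$EMAX
  if (mx <= 0)
    stop("patient maximum state BASE + EMAX must be positive to derive targets")
  target_spec(theta = 0.3 * mx, theta_min = 0.2 * mx, theta_max = 0.4 * mx,
              theta_t = 0.1 * mx)
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Schedule objectives
#'
#' The four optimization criteria: total medication, squared deviation
#' from the optimal state, (squared) area outside the target range, and
#' (squared) area below the threshold. The integral criteria use the
#' trapezoidal rule on the trace grid, so their units are TRS^2 x minutes
#' (TRS x minutes when `squared = FALSE`).
#'
#' @param schedule a [dose_schedule()].
#' @return `objective_dose_sum`: total dose in mg.
#' @export
objective_dose_sum <- function(schedule) sum(schedule$sizes)

#' @rdname objective_dose_sum
#' @param trace a [state_trace()].
#' @param target a [target_spec()].
#' @export
objective_sq_deviation <- function(trace, target) {
  trapezoid(trace$times, (trace$values - target$theta)^2)
}

#' @rdname objective_dose_sum
#' @param squared square the excursion before integrating (default); the
#'   unsquared reading integrates the plain excursion.
#' @export
objective_outside_range <- function(trace, target, squared = TRUE) {
  if (!(target$theta_min < target$theta_max))
    stop("theta_min must be below theta_max")
  pen <- pmax(0, target$theta_min - trace$values,
              trace$values - target$theta_max)
  trapezoid(trace$times, if (squared) pen^2 else pen)
}

#' @rdname objective_dose_sum
#' @export
objective_below_threshold <- function(trace, target, squared = TRUE) {
  pen <- pmax(0, target$theta_t - trace$values)
  trapezoid(trace$times, if (squared) pen^2 else pen)
}

#' Weights for the combined objective
#'
#' @param w_dose weight of the total-dose criterion.
#' @param w_dev weight of the squared-deviation criterion.
#' @param w_range weight of the area outside the target range.
#' @param w_threshold weight of the area below the threshold, used as a
#'   penalty during free optimization.
#' @param squared use the squared-excursion reading of the area criteria.
#' @param threshold_mode `"penalty"` adds the weighted below-threshold
#'   area; `"hard"` returns `Inf` when the threshold condition after the
#'   first dose is violated (the exhaustive-benchmark convention).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(w_dose = 0, w_dev = 0, w_range = 1,
                           w_threshold = 10, squared = TRUE,
                           threshold_mode = c("penalty", "hard")) {
  w <- c(w_dose, w_dev, w_range, w_threshold)
  if (any(w < 0) || all(w == 0))
    stop("objective weights must be non-negative and not all zero")
  structure(list(w_dose = w_dose, w_dev = w_dev, w_range = w_range,
                 w_threshold = w_threshold, squared = isTRUE(squared),
                 threshold_mode = match.arg(threshold_mode)),
            class = "objective_spec")
}

# Below-threshold area counted only after the state first reaches the
# threshold following the first dose (no onset -> the whole post-dose day
# counts, so never reaching the threshold is penalized heavily).
below_threshold_after_onset <- function(trace, target, after_time = 0,
                                        squared = TRUE) {
  idx <- which(trace$times >= after_time)
  v <- trace$values[idx]; tt <- trace$times[idx]
  i0 <- which(v >= target$theta_t)[1]
  if (!is.na(i0)) { v <- v[i0:length(v)]; tt <- tt[i0:length(tt)] }
  pen <- pmax(0, target$theta_t - v)
  trapezoid(tt, if (squared) pen^2 else pen)
}

# Threshold condition of the comparison method: after the first dose has
# brought the state up to the threshold, it must never fall below it
# again (and it must reach it at all).
threshold_ok <- function(trace, target, after_time = 0) {
  idx <- which(trace$times >= after_time)
  v <- trace$values[idx]
  i0 <- which(v >= target$theta_t)[1]
  if (is.na(i0)) return(FALSE)
  all(v[i0:length(v)] >= target$theta_t - 1e-12)
}

#' Combined schedule objective
#'
#' Evaluates a schedule by simulating or predicting its day trace with the
#' supplied evaluator and combining the weighted criteria.
#'
#' @param schedule a [dose_schedule()].
#' @param evaluator function mapping a schedule to a [state_trace()]
#'   (see [pkpd_evaluator()] / [ml_evaluator()]).
#' @param spec an [objective_spec()].
#' @param target a [target_spec()].
#' @return Objective score (numeric scalar).
#' @export
combined_objective <- function(schedule, evaluator, spec, target) {
  trace <- tryCatch(evaluator(schedule), error = function(e)
    stop(sprintf("schedule evaluator failed for schedule [%s]: %s",
                 paste(schedule$times, collapse = ","), conditionMessage(e))))
  score <- 0
  if (spec$w_dose > 0) score <- score + spec$w_dose * objective_dose_sum(schedule)
  if (spec$w_dev > 0)
    score <- score + spec$w_dev * objective_sq_deviation(trace, target)
  if (spec$w_range > 0)
    score <- score + spec$w_range *
      objective_outside_range(trace, target, spec$squared)
  if (spec$w_threshold > 0) {
    first_dose <- if (length(schedule$times)) min(schedule$times) else 0
    if (spec$threshold_mode == "hard") {
      if (!threshold_ok(trace, target, first_dose)) return(Inf)
    } else {
      # the threshold applies once the first dose has taken effect: the
      # unavoidable morning ramp up to the first crossing is not penalized
      score <- score + spec$w_threshold *
        below_threshold_after_onset(trace, target, first_dose, spec$squared)
    }
  }
  score
}

#' Schedule evaluators
#'
#' An evaluator maps a [dose_schedule()] to the day's [state_trace()].
#' `pkpd_evaluator` simulates the patient's compartmental model (the
#' one-step propagator is precomputed, so repeated calls inside an
#' optimizer are cheap); `ml_evaluator` rolls out a trained response
#' model from the patient's wake state.
#'
#' @param params a [patient_params()].
#' @param day_length minutes awake.
#' @param grid_step sampling step (minutes).
#' @param initial initial compartment state (pkpd) — defaults to the
#'   endogenous steady state.
#' @return A function `schedule -> state_trace`.
#' @export
pkpd_evaluator <- function(params, day_length, grid_step = 10,
                           initial = steady_state(params)) {
  st <- pkpd_stepper(params, grid_step)
  times <- seq(0, day_length - grid_step, by = grid_step)
  n <- length(times)
  x0 <- as.numeric(initial)
  force(params)
  function(schedule) {
    dose_at <- numeric(n)
    if (length(schedule$times)) {
      idx <- round(schedule$times / grid_step) + 1
      keep <- idx >= 1 & idx <= n
      for (j in which(keep))
        dose_at[idx[j]] <- dose_at[idx[j]] + schedule$sizes[j]
    }
    x <- x0
    ce <- numeric(n)
    for (i in seq_len(n)) {
      ce[i] <- x[4]
      x[1] <- x[1] + dose_at[i]
      x <- c(st$Phi %*% x) + st$psi
    }
    state_trace(times, effect_from_concentration(pmax(ce, 0), params),
                day_length)
  }
}

#' @rdname pkpd_evaluator
#' @param model a trained `response_model`.
#' @param initial_state the patient's wake TRS score.
#' @export
ml_evaluator <- function(model, initial_state, day_length, grid_step = 10) {
  n_steps <- day_length / grid_step - 1
  function(schedule) {
    tr <- rollout_predict(model, initial_state, schedule, n_steps, grid_step)
    tr$day_length <- day_length
    tr
  }
}
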