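#' Size of the discrete dosing action space
#'
#' Action `a` maps to a dose of `a * dose_step` mg; action 0 is "no
#' medication", so a patient with a 400 mg maximum dose and a 25 mg dose
#' step has 17 available actions.
#'
#' @param max_dose maximum dose (mg).
#' @param dose_step dose step (mg); must divide `max_dose`.
#' @export
action_space_size <- function(max_dose, dose_step) {
  if (abs(max_dose / dose_step - round(max_dose / dose_step)) > 1e-9)
    stop("dose_step must divide max_dose")
  as.integer(floor(max_dose / dose_step) + 1L)
}

#' Dosing-environment configuration
#'
#' @param dose_step dose step (mg), typically 5 or 50.
#' @param max_dose maximum dose (mg).
#' @param min_interdose_interval lockout between doses (minutes).
#' @param grid_step simulation step (minutes).
#' @param max_steps episode truncation (grid steps; 110 steps is over
#'   18 hours, longer than a typical waking day).
#' @param termination_max_state TRS level whose exceedance terminates the
#'   episode (patient-specific dyskinesia guard); `NULL` defaults to
#'   halfway between the target ceiling and the patient's maximum effect.
#' @param backend `"pkpd"`, `"history"` or `"impulse"`.
#' @return An object of class `env_config`.
#' @export
env_config <- function(dose_step = 50, max_dose = 400,
                       min_interdose_interval = 90, grid_step = 10,
                       max_steps = 110, termination_max_state = NULL,
                       backend = c("pkpd", "history", "impulse")) {
  backend <- match.arg(backend)
  structure(list(dose_step = dose_step, max_dose = max_dose,
                 min_interdose_interval = min_interdose_interval,
                 grid_step = grid_step, max_steps = as.integer(max_steps),
                 termination_max_state = termination_max_state,
                 backend = backend,
                 n_actions = action_space_size(max_dose, dose_step),
                 lockout_steps =
                   as.integer(ceiling(min_interdose_interval / grid_step))),
            class = "env_config")
}

#' Reward of a traversed state segment
#'
#' The negative trapezoidal area outside the target range over a sequence
#' of consecutive grid states; summing segment rewards over an episode
#' reproduces the negative whole-day score.
#'
#' @param states TRS values at consecutive grid points.
#' @param target a [target_spec()].
#' @param grid_step grid step (minutes).
#' @export
segment_reward <- function(states, target, grid_step = 10) {
  if (!length(states)) stop("need at least one state")
  if (length(states) == 1) return(0)
  pen <- pmax(0, target$theta_min - states, states - target$theta_max)
  -trapezoid(seq(0, by = grid_step, length.out = length(states)), pen^2)
}

#' Create a stepwise dosing environment
#'
#' An episodic reinforcement-learning environment over one medication
#' day. Actions are discrete dose choices; action 0 advances the clock
#' one grid step, a dosing action administers the dose and then
#' auto-advances through the lockout window (ceiling(90/10) = 9 steps by
#' default), accumulating reward along the way. The reward is the
#' negative area outside the target range of the traversed segment. The
#' episode terminates when the state exceeds the patient's termination
#' level and truncates after `max_steps` grid steps.
#'
#' The observation depends on the backend: the PK/PD backend exposes the
#' compartment vector `(a0, a1, a2, ce)`; the history backend the
#' `2k + 1` values (recent state, k dose sizes, k elapsed times); the
#' impulse backend the LSTM's internal cell values, each within
#' `[-1, 1]`.
#'
#' @param params a [patient_params()] (always required for targets; the
#'   pkpd backend also simulates with it).
#' @param cfg an [env_config()].
#' @param target a [target_spec()]; defaults to [target_from_patient()].
#' @param model a trained `response_model`, required for the ML backends.
#' @return An object of class `dosing_env` (mutable environment).
#' @export
dosing_env <- function(params, cfg = env_config(), target = NULL,
                       model = NULL) {
  target <- if (is.null(target)) target_from_patient(params) else target
  if (cfg$backend != "pkpd") {
    if (is.null(model) || !isTRUE(model$trained))
      stop(sprintf("backend '%s' needs a trained response model", cfg$backend))
    if (cfg$backend == "impulse" && model$cfg$type != "impulse")
      stop("impulse backend needs an impulse model")
    if (cfg$backend == "history" && model$cfg$type != "history")
      stop("history backend needs a history model")
  }
  max_eff <- params$BASE + params$EMAX
  term_max <- if (is.null(cfg$termination_max_state))
    target$theta_max + 0.5 * (max_eff - target$theta_max)
  else cfg$termination_max_state
  e <- new.env(parent = emptyenv())
  e$params <- params; e$cfg <- cfg; e$target <- target; e$model <- model
  e$term_max <- term_max
  e$stepper <- if (cfg$backend == "pkpd")
    pkpd_stepper(params, cfg$grid_step) else NULL
  class(e) <- "dosing_env"
  env_reset(e)
  e
}

env_observation <- function(e) {
  cfg <- e$cfg
  if (cfg$backend == "pkpd") {
    obs <- e$x
  } else if (cfg$backend == "history") {
    k <- e$model$cfg$k_prev_doses
    now <- e$step_count * cfg$grid_step
    obs <- c(e$s, numeric(2 * k))
    dh <- e$dose_history
    if (nrow(dh)) {
      recent <- dh[order(dh$time, decreasing = TRUE), , drop = FALSE]
      recent <- recent[seq_len(min(k, nrow(recent))), , drop = FALSE]
      for (j in seq_len(nrow(recent))) {
        obs[1 + j] <- recent$size[j]
        obs[1 + k + j] <- now - recent$time[j]
      }
    }
  } else {
    obs <- c(e$h, pmin(pmax(e$c, -1), 1))
  }
  as.numeric(obs)
}

#' Reset the dosing environment
#'
#' Clears the clock, dose history and accumulated state. The PK/PD
#' backend restarts from the endogenous steady state; the impulse backend
#' from a zero recurrent cell state.
#'
#' @param e a [dosing_env()].
#' @param seed optional seed (the dynamics are deterministic; kept for
#'   interface compatibility).
#' @return List with `observation` and `info`.
#' @export
env_reset <- function(e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- e$cfg
  e$step_count <- 0L
  e$dose_history <- data.frame(time = numeric(0), size = numeric(0))
  e$last_dose_step <- -Inf
  e$states <- numeric(0)
  if (cfg$backend == "pkpd") {
    e$x <- as.numeric(steady_state(e$params))
    e$s <- effect_from_concentration(e$x[4], e$params)
  } else {
    e$s <- effect_from_concentration(steady_state(e$params)[["ce"]],
                                     e$params)
    if (cfg$backend == "impulse") {
      u <- e$model$cfg$lstm_units
      e$h <- numeric(u); e$c <- numeric(u)
    }
  }
  e$states <- e$s
  list(observation = env_observation(e),
       info = list(time = 0, doses = e$dose_history))
}

# advance the simulation by one grid step with the given dose (mg)
# administered at the current clock time
env_advance <- function(e, dose) {
  cfg <- e$cfg
  s_prev <- e$s
  if (cfg$backend == "pkpd") {
    e$x[1] <- e$x[1] + dose
    e$x <- c(e$stepper$Phi %*% e$x) + e$stepper$psi
    e$s <- effect_from_concentration(max(e$x[4], 0), e$params)
  } else if (cfg$backend == "impulse") {
    m <- e$model; norm <- m$norm; P <- m$params; mc <- m$cfg
    u <- mc$lstm_units
    x <- c((e$s - norm$x_mean[1]) / norm$x_sd[1],
           (dose - norm$x_mean[2]) / norm$x_sd[2])
    Z <- as.numeric(x %*% P$Wx) + as.numeric(e$h %*% P$Wh) + P$b
    gi <- sigmoid(Z[seq_len(u)]); gf <- sigmoid(Z[u + seq_len(u)])
    gg <- tanh(Z[2 * u + seq_len(u)]); go <- sigmoid(Z[3 * u + seq_len(u)])
    e$c <- gf * e$c + gi * gg
    e$h <- go * tanh(e$c)
    fw <- dense_forward(head_layers(P), matrix(e$h, 1))
    mo <- map_output(fw$out, e$s, mc, norm)
    e$s <- mo$s
  } else {
    m <- e$model; mc <- m$cfg
    k <- mc$k_prev_doses
    now <- (e$step_count + 1L) * cfg$grid_step  # time of the predicted state
    feats <- numeric(2 * k)
    dh <- rbind(e$dose_history,
                if (dose > 0) data.frame(time = e$step_count * cfg$grid_step,
                                         size = dose))
    if (nrow(dh)) {
      recent <- dh[order(dh$time, decreasing = TRUE), , drop = FALSE]
      recent <- recent[seq_len(min(k, nrow(recent))), , drop = FALSE]
      for (j in seq_len(nrow(recent))) {
        feats[2 * j - 1] <- now - recent$time[j]
        feats[2 * j] <- recent$size[j]
      }
    }
    x_raw <- c(rep(e$s, mc$n_prev_states), feats)
    x <- (x_raw - m$norm$x_mean) / m$norm$x_sd
    fw <- dense_forward(head_layers(m$params), matrix(x, 1))
    mo <- map_output(fw$out, e$s, mc, m$norm)
    e$s <- mo$s
  }
  if (dose > 0) {
    e$dose_history <- rbind(e$dose_history,
                            data.frame(time = e$step_count * cfg$grid_step,
                                       size = dose))
    e$last_dose_step <- e$step_count
  }
  e$step_count <- e$step_count + 1L
  e$states <- c(e$states, e$s)
  segment_reward(c(s_prev, e$s), e$target, cfg$grid_step)
}

#' Step the dosing environment
#'
#' @param e a [dosing_env()].
#' @param action integer in `0 .. n_actions - 1`; the dose administered
#'   is `action * dose_step` mg.
#' @return List with `observation`, `reward`, `terminated`, `truncated`
#'   and `info`.
#' @export
env_step <- function(e, action) {
  cfg <- e$cfg
  action <- as.integer(action)
  if (is.na(action) || action < 0 || action >= cfg$n_actions)
    stop(sprintf("action must be an integer in [0, %d]", cfg$n_actions - 1))
  dose <- action * cfg$dose_step
  reward <- 0
  terminated <- FALSE; truncated <- FALSE
  n_adv <- if (dose > 0) cfg$lockout_steps else 1L
  for (i in seq_len(n_adv)) {
    reward <- reward + env_advance(e, if (i == 1) dose else 0)
    if (e$s > e$term_max) {
      terminated <- TRUE
      # ending the day early must never pay: charge the remaining day as
      # if the state stayed at the termination excursion level
      reward <- reward - (cfg$max_steps - e$step_count) * cfg$grid_step *
        (e$term_max - e$target$theta_max)^2
      break
    }
    if (e$step_count >= cfg$max_steps) { truncated <- TRUE; break }
  }
  list(observation = env_observation(e), reward = reward,
       terminated = terminated, truncated = truncated,
       info = list(time = e$step_count * cfg$grid_step,
                   state = e$s, doses = e$dose_history))
}

#' Extract a schedule from a policy
#'
#' Rolls the policy out deterministically (greedy action) from reset,
#' records the dose events as a [dose_schedule()] and returns the
#' negative cumulative reward as the score; optionally re-scores the
#' schedule with a PK/PD evaluator for cross-backend comparability.
#'
#' @param policy a policy trained by [train_agent()], or any function
#'   mapping an observation to an action.
#' @param e a [dosing_env()].
#' @param rescore_evaluator optional evaluator used to recompute the
#'   schedule's objective (e.g. [pkpd_evaluator()]).
#' @param target target used with `rescore_evaluator`.
#' @return List with `schedule`, `score`, `reward`, `states` and
#'   optionally `score_rescored`.
#' @export
extract_schedule <- function(policy, e, rescore_evaluator = NULL,
                             target = NULL) {
  act <- if (is.function(policy)) policy
  else function(obs) policy_action(policy, obs, deterministic = TRUE)
  res <- env_reset(e)
  total <- 0
  repeat {
    st <- env_step(e, act(res$observation))
    total <- total + st$reward
    res <- st
    if (st$terminated || st$truncated) break
  }
  out <- list(schedule = dose_schedule(e$dose_history$time,
                                       e$dose_history$size),
              score = -total, reward = total, states = e$states)
  if (!is.null(rescore_evaluator)) {
    tr <- rescore_evaluator(out$schedule)
    out$score_rescored <- objective_outside_range(
      tr, if (is.null(target)) e$target else target)
  }
  out
}
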