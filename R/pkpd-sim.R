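#' Sigmoid-Emax effect law
#'
#' Maps an effect-compartment concentration to a TRS score:
#' `BASE + EMAX * ce^gamma / (ce^gamma + EC50^gamma)`. The result always
#' lies inside `[BASE, BASE + EMAX]`.
#'
#' @param ce effect-compartment concentration (mg/L), non-negative;
#'   vectorized.
#' @param params a [patient_params()].
#' @return TRS score(s).
#' @export
effect_from_concentration <- function(ce, params) {
  if (any(ce < 0)) stop("effect-compartment concentration must be >= 0")
  cg <- ce^params$gamma
  params$BASE + params$EMAX * cg / (cg + params$EC50^params$gamma)
}

#' Time derivatives of the compartmental system
#'
#' The pharmacokinetic side is a three-compartment linear system (gut
#' depot `a0`, central `a1`, peripheral `a2`, amounts in mg) with an
#' endogenous synthesis input, coupled to a first-order effect compartment
#' concentration `ce` (mg/L):
#' \deqn{a0' = Inf - ka a0}
#' \deqn{a1' = BIO ka a0 - ((Q+CL)/V1) a1 + (Q/V2) a2 + Rsyn}
#' \deqn{a2' = (Q/V1) a1 - (Q/V2) a2}
#' \deqn{ce' = kEO (a1/V1 - ce)}
#'
#' @param state named numeric `(a0, a1, a2, ce)`.
#' @param params a [patient_params()].
#' @param inf_rate continuous infusion rate (mg/min); 0 for oral dosing.
#' @return Named numeric vector of derivatives.
#' @export
pkpd_derivatives <- function(state, params, inf_rate = 0) {
  if (any(state < -1e-12)) stop("compartment state must be non-negative")
  if (inf_rate < 0) stop("infusion rate must be non-negative")
  a0 <- state[["a0"]]; a1 <- state[["a1"]]; a2 <- state[["a2"]]
  ce <- state[["ce"]]
  with(params, c(
    a0 = inf_rate - ka * a0,
    a1 = BIO * ka * a0 - (Q + CL) / V1 * a1 + Q / V2 * a2 + Rsyn,
    a2 = Q / V1 * a1 - Q / V2 * a2,
    ce = kEO * (a1 / V1 - ce)
  ))
}

# Linear system matrices: x' = A x + b for x = (a0, a1, a2, ce).
pkpd_system <- function(params) {
  with(params, {
    A <- matrix(c(
      -ka,           0,              0,        0,
      BIO * ka,     -(Q + CL) / V1,  Q / V2,   0,
      0,             Q / V1,        -Q / V2,   0,
      0,             kEO / V1,       0,       -kEO), 4, 4, byrow = TRUE)
    list(A = A, b = c(0, Rsyn, 0, 0))
  })
}

#' Endogenous steady state
#'
#' With no medication the system settles at `a0 = 0`,
#' `a1 = Rsyn * V1 / CL`, `a2 = (V2/V1) * a1`, `ce = a1 / V1`.
#'
#' @param params a [patient_params()].
#' @return Named numeric `(a0, a1, a2, ce)`.
#' @export
steady_state <- function(params) {
  a1 <- params$Rsyn * params$V1 / params$CL
  c(a0 = 0, a1 = a1, a2 = params$V2 / params$V1 * a1, ce = a1 / params$V1)
}

# Exact one-step propagator for the linear PK system over a fixed step:
# x(t+dt) = Phi x(t) + psi, Phi = expm(A dt), psi = A^-1 (Phi - I) b.
pkpd_stepper <- function(params, dt) {
  sys <- pkpd_system(params)
  Phi <- as.matrix(Matrix::expm(sys$A * dt))
  psi <- as.numeric(solve(sys$A, (Phi - diag(4)) %*% sys$b))
  list(Phi = Phi, psi = psi)
}

#' Simulate a TRS trace for one day
#'
#' Integrates the compartmental system over a waking day under an oral
#' dose schedule. Each oral dose is an instantaneous bolus added to the
#' absorption compartment `a0` at its intake time (first-order oral
#' absorption; the infusion term stays 0), and affects states strictly
#' after that time. The effect law is applied to `ce` on the sampling
#' grid `t = 0, step, ..., day_length - step`.
#'
#' @param params a [patient_params()].
#' @param schedule a [dose_schedule()]; times must be grid-aligned and
#'   inside `[0, day_length]`.
#' @param day_length minutes awake; must be a multiple of `grid_step`.
#' @param grid_step sampling step (minutes, default 10).
#' @param initial initial compartment state; defaults to the endogenous
#'   steady state at wake.
#' @param method `"exact"` steps the linear system with its matrix
#'   exponential (exact on the grid); `"ode"` uses adaptive `lsoda`
#'   integration restarted at each dose event (tolerances 1e-8/1e-10).
#' @return A [state_trace()].
#' @export
simulate_trace <- function(params, schedule = dose_schedule(),
                           day_length, grid_step = 10,
                           initial = steady_state(params),
                           method = c("exact", "ode")) {
  method <- match.arg(method)
  if (day_length <= 0 || abs(day_length / grid_step -
                             round(day_length / grid_step)) > 1e-8)
    stop("grid_step must divide day_length")
  if (length(schedule$times) &&
      (any(schedule$times < 0) || any(schedule$times > day_length)))
    stop("dose times must lie within [0, day_length]")
  times <- seq(0, day_length - grid_step, by = grid_step)
  n <- length(times)
  dose_at <- numeric(n)
  if (length(schedule$times)) {
    idx <- round(schedule$times / grid_step) + 1
    if (max(abs(schedule$times / grid_step - round(schedule$times / grid_step))) > 1e-8)
      stop("dose times must be aligned to the sampling grid")
    for (j in seq_along(idx)) {
      if (idx[j] <= n) dose_at[idx[j]] <- dose_at[idx[j]] + schedule$sizes[j]
    }
  }
  x <- as.numeric(initial)
  values <- numeric(n)
  if (method == "exact") {
    st <- pkpd_stepper(params, grid_step)
    for (i in seq_len(n)) {
      values[i] <- x[4]
      x[1] <- x[1] + dose_at[i]
      x <- st$Phi %*% x
      x <- c(x) + st$psi
    }
  } else {
    derivs <- function(t, y, parms) {
      names(y) <- c("a0", "a1", "a2", "ce")
      list(pkpd_derivatives(y, params))
    }
    for (i in seq_len(n)) {
      values[i] <- x[4]
      x[1] <- x[1] + dose_at[i]
      sol <- deSolve::lsoda(y = x, times = c(0, grid_step), func = derivs,
                            rtol = 1e-8, atol = 1e-10)
      x <- as.numeric(sol[2, -1])
    }
  }
  state_trace(times, effect_from_concentration(pmax(values, 0), params),
              day_length)
}

#' Simulate compartment amounts on the grid
#'
#' Like [simulate_trace()] but returns the raw compartment matrix instead
#' of TRS scores; used for diagnostics and tests.
#'
#' @inheritParams simulate_trace
#' @return Matrix with columns `a0, a1, a2, ce`, one row per grid point.
#' @export
simulate_compartments <- function(params, schedule = dose_schedule(),
                                  day_length, grid_step = 10,
                                  initial = steady_state(params)) {
  times <- seq(0, day_length - grid_step, by = grid_step)
  n <- length(times)
  dose_at <- numeric(n)
  if (length(schedule$times)) {
    idx <- round(schedule$times / grid_step) + 1
    for (j in seq_along(idx))
      if (idx[j] <= n) dose_at[idx[j]] <- dose_at[idx[j]] + schedule$sizes[j]
  }
  st <- pkpd_stepper(params, grid_step)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("a0", "a1", "a2", "ce")))
  x <- as.numeric(initial)
  for (i in seq_len(n)) {
    out[i, ] <- x
    x[1] <- x[1] + dose_at[i]
    x <- c(st$Phi %*% x) + st$psi
  }
  out
}
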