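# Shared fixtures: a representative mid-population patient, small
# cohorts and quick model constructors. Everything is generated in code.

test_patient <- function(...) {
  args <- list(ka = 0.028, BIO = 0.85, Q = 0.58, V1 = 11, V2 = 27,
               CL = 0.52, Rsyn = 0.15, kEO = 0.04, BASE = -2, EMAX = 4.3,
               EC50 = 1.5, gamma = 2.2)
  override <- list(...)
  for (nm in names(override)) args[[nm]] <- override[[nm]]
  do.call(patient_params, args)
}

test_population <- function() default_population()

# small synthetic day for feature/rollout tests (not PK/PD-derived)
toy_day <- function(T = 12, seed = 1, schedule = dose_schedule(c(0, 40),
                                                              c(100, 150))) {
  set.seed(seed)
  times <- seq(0, T * 10, by = 10)
  list(schedule = schedule,
       trace = state_trace(times, cumsum(stats::rnorm(T + 1, 0, 0.2))))
}

# linear dynamics oracle: s_{t+1} = decay * s_t + gain * dose_t
linear_day <- function(seed, T = 60, decay = 0.9, gain = 0.001) {
  set.seed(seed)
  nd <- sample(3:6, 1)
  dt <- sort(sample(seq(10, T * 10, by = 10), nd))
  dz <- sample(seq(50, 400, 50), nd, replace = TRUE)
  sch <- dose_schedule(dt, dz)
  dose_at <- numeric(T)
  for (j in seq_along(dt)) dose_at[dt[j] / 10] <- dose_at[dt[j] / 10] + dz[j]
  s <- numeric(T + 1)
  s[1] <- -1
  for (t in seq_len(T)) s[t + 1] <- decay * s[t] + gain * dose_at[t]
  list(schedule = sch, trace = state_trace(seq(0, T * 10, by = 10), s))
}

# an identity-normalized untrained model usable for rollout mechanics
mechanical_model <- function(cfg, seed = 3) {
  m <- init_model(cfg, seed = seed)
  width <- if (cfg$type == "history")
    cfg$n_prev_states + 2 * cfg$k_prev_doses else 2
  m$norm <- pdsched:::identity_normalizer(width)
  m$trained <- TRUE
  m
}
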