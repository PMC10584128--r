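test_that("action space size follows the dose step", {
  expect_equal(action_space_size(400, 25), 17)
  expect_equal(action_space_size(400, 400), 2)
  expect_equal(action_space_size(400, 50), 9)
  expect_error(action_space_size(400, 30), "divide")
})

test_that("reset restores the endogenous steady state and clears history", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 100, max_dose = 400))
  r1 <- env_reset(e, seed = 1)
  expect_equal(r1$observation, unname(steady_state(p)))
  expect_equal(nrow(r1$info$doses), 0)
  env_step(e, 2)
  r2 <- env_reset(e, seed = 1)
  expect_identical(r1$observation, r2$observation)
  expect_equal(e$step_count, 0L)
})

test_that("step advances one grid step, dosing auto-advances the lockout", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 50, max_dose = 400))
  env_reset(e)
  st <- env_step(e, 0)
  expect_equal(e$step_count, 1L)
  st <- env_step(e, 2)   # 100 mg -> ceil(90/10) = 9 auto-advances
  expect_equal(e$step_count, 10L)
  expect_error(env_step(e, 9), "action")
  expect_error(env_step(e, -1), "action")
})

test_that("110 in-range steps truncate without terminating", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 50, max_dose = 400))
  env_reset(e)
  n <- 0
  repeat {
    st <- env_step(e, 0)   # never dosing keeps the state at baseline
    n <- n + 1
    if (st$terminated || st$truncated) break
  }
  expect_equal(n, 110)
  expect_true(st$truncated)
  expect_false(st$terminated)
})

test_that("segment rewards reproduce closed forms and are additive", {
  tg <- target_spec(1, 0.5, 1.5, 0.3)
  expect_equal(segment_reward(rep(1, 5), tg), 0)
  expect_equal(segment_reward(c(2.5, 2.5), tg), -10)   # 1^2 * 10 min
  expect_equal(segment_reward(0.9, tg), 0)             # single state
  set.seed(6)
  states <- runif(21, -2, 3)
  whole <- segment_reward(states, tg)
  parts <- segment_reward(states[1:11], tg) + segment_reward(states[11:21], tg)
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("episode reward equals the negative whole-day trace score", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 100, max_dose = 200))
  tg <- e$target
  env_reset(e)
  total <- 0
  set.seed(3)
  repeat {
    a <- sample(0:1, 1, prob = c(0.5, 0.5))
    st <- env_step(e, a)
    total <- total + st$reward
    if (st$terminated || st$truncated) break
  }
  expect_false(st$terminated)
  sch <- dose_schedule(e$dose_history$time, e$dose_history$size)
  tr <- simulate_trace(p, sch, day_length = length(e$states) * 10)
  expect_equal(-total, objective_outside_range(tr, tg), tolerance = 1e-6)
})

test_that("terminating early never pays more than staying in range", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 200, max_dose = 400))
  overdose <- function() {
    env_reset(e); total <- 0
    repeat {
      st <- env_step(e, 2)
      total <- total + st$reward
      if (st$terminated || st$truncated) break
    }
    list(total = total, terminated = st$terminated)
  }
  sane <- function() {
    env_reset(e); total <- 0
    repeat {
      st <- env_step(e, 1)
      total <- total + st$reward
      if (st$terminated || st$truncated) break
    }
    total
  }
  od <- overdose()
  expect_true(od$terminated)
  expect_lt(od$total, sane())
})

test_that("extracted schedules honor the lockout and match the reward", {
  p <- test_patient()
  e <- dosing_env(p, env_config(dose_step = 100, max_dose = 200))
  set.seed(12)
  policy_fn <- function(obs) sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
  ex <- extract_schedule(policy_fn, e,
                         rescore_evaluator = pkpd_evaluator(p, 1110))
  if (n_doses(ex$schedule) > 1)
    expect_true(all(diff(ex$schedule$times) >= 90))
  expect_equal(ex$score, -ex$reward)
  # a policy that never doses yields an empty schedule
  ex0 <- extract_schedule(function(obs) 0L, e)
  expect_equal(n_doses(ex0$schedule), 0)
})

test_that("ML-backed environments expose the documented observations", {
  p <- test_patient()
  days <- lapply(1:10, function(i) linear_day(i, T = 40))
  gen <- train_general(days, impulse_model_config(lstm_units = 4,
                                                  hidden_sizes = c(8, 8)),
                       train_config(max_epochs = 10, patience = 9, seed = 2))
  e <- dosing_env(p, env_config(dose_step = 100, max_dose = 200,
                                backend = "impulse"), model = gen$model)
  r <- env_reset(e)
  expect_equal(length(r$observation), 2 * 4)  # h and c for 4 units
  expect_true(all(r$observation >= -1 & r$observation <= 1))
  for (i in 1:20) {
    st <- env_step(e, sample(0:2, 1))
    expect_true(all(st$observation >= -1 & st$observation <= 1))
    if (st$terminated || st$truncated) break
  }
  genh <- train_general(days, history_model_config(hidden_sizes = c(8, 8)),
                        train_config(max_epochs = 5, patience = 4, seed = 2))
  eh <- dosing_env(p, env_config(dose_step = 100, max_dose = 200,
                                 backend = "history"), model = genh$model)
  rh <- env_reset(eh)
  expect_equal(length(rh$observation), 2 * 2 + 1)  # 2k + 1 with k = 2
  expect_error(dosing_env(p, env_config(backend = "impulse")), "model")
})
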