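test_that("decision-vector dimensions follow the constraint table", {
  sch4 <- schedule_from_intervals(30, c(120, 150, 180), c(100, 50, 50, 75))
  none <- constraint_set()
  v <- encode_schedule(sch4, none)
  expect_equal(length(v), 8)
  expect_equal(v, c(30, 120, 150, 180, 100, 50, 50, 75))
  all4 <- constraints_from_numbers(1:4)
  sch_c <- schedule_from_intervals(0, rep(120, 3), c(200, 100, 100, 100))
  v4 <- encode_schedule(sch_c, all4)
  expect_equal(length(v4), 3)      # [dt, d_mor, d_main]
  expect_equal(v4, c(120, 200, 100))
  expect_error(encode_schedule(sch4, constraints_from_numbers(2)), "wake")
  expect_error(encode_schedule(sch4, constraints_from_numbers(4)), "equal")
})

test_that("encode/decode is a round trip on random valid schedules", {
  set.seed(4)
  combos <- list(integer(0), 1, c(1, 2), c(2, 3), c(3, 4), 1:4)
  for (cs in combos) {
    con <- constraints_from_numbers(cs)
    for (rep in 1:10) {
      n <- sample(2:6, 1)
      t1 <- if (con$c2) 0 else sample(0:5, 1) * 10
      ivs <- if (con$c4) rep(sample(9:20, 1) * 10, n - 1)
      else sample(9:20, n - 1, replace = TRUE) * 10
      sizes <- if (con$c3) c(sample(1:8, 1) * 50,
                             rep(sample(0:6, 1) * 50, n - 1))
      else sample(0:8, n, replace = TRUE) * 50
      sch <- schedule_from_intervals(t1, ivs, sizes)
      back <- decode_schedule(encode_schedule(sch, con), con, n)
      expect_equal(back$times, sch$times)
      expect_equal(back$sizes, sch$sizes)
    }
  }
  expect_error(decode_schedule(c(1, 2), constraints_from_numbers(1:4), 4),
               "length")
})

test_that("patient targets follow the 10/20-40% rule", {
  t1 <- target_from_patient(test_patient(BASE = -3, EMAX = 6))
  expect_equal(t1$theta_t, 0.3)
  expect_equal(c(t1$theta_min, t1$theta_max), c(0.6, 1.2))
  expect_equal(t1$theta, 0.9)
  t2 <- target_from_patient(test_patient(BASE = -2, EMAX = 3))
  expect_equal(t2$theta_t, 0.1)
  expect_equal(c(t2$theta_min, t2$theta_max), c(0.2, 0.4))
  expect_lt(t2$theta_min, t2$theta_max)
  expect_error(target_from_patient(test_patient(BASE = -2, EMAX = 1.5)),
               "positive")
})

test_that("objectives reproduce constant-trace closed forms", {
  tg <- target_spec(1, 0.5, 1.5, 0.3)
  L <- 300
  times <- seq(0, L, by = 10)
  flat <- function(v) state_trace(times, rep(v, length(times)))
  expect_equal(objective_dose_sum(dose_schedule(c(0, 90), c(100, 150))), 250)
  expect_equal(objective_dose_sum(dose_schedule()), 0)
  expect_equal(objective_sq_deviation(flat(1), tg), 0)
  expect_equal(objective_sq_deviation(flat(1.5), tg), 0.25 * L)
  expect_equal(objective_outside_range(flat(1), tg), 0)
  expect_equal(objective_outside_range(flat(2.5), tg), 1 * L)
  expect_equal(objective_outside_range(flat(-1.5), tg), 4 * L)
  expect_equal(objective_below_threshold(flat(1), tg), 0)
  expect_equal(objective_below_threshold(flat(-0.7), tg), 1 * L)
  # unsquared reading
  expect_equal(objective_outside_range(flat(2.5), tg, squared = FALSE),
               1 * L)
  expect_equal(objective_outside_range(flat(3.5), tg, squared = FALSE),
               2 * L)
})

test_that("area objectives are additive over disjoint sub-intervals", {
  tg <- target_spec(1, 0.5, 1.5, 0.3)
  set.seed(2)
  v <- runif(31, -2, 3)
  tr <- state_trace(seq(0, 300, 10), v)
  left <- state_trace(seq(0, 150, 10), v[1:16])
  right <- state_trace(seq(150, 300, 10), v[16:31])
  expect_equal(objective_below_threshold(tr, tg),
               objective_below_threshold(left, tg) +
                 objective_below_threshold(right, tg))
})

test_that("grid refinement changes smooth-trace integrals by < 1%", {
  # a dose-free relaxation from a displaced initial state is smooth
  p <- test_patient()
  tg <- target_from_patient(p)
  x0 <- steady_state(p)
  x0[["a1"]] <- x0[["a1"]] + 40
  coarse <- simulate_trace(p, dose_schedule(), 600, grid_step = 10,
                           initial = x0)
  fine <- simulate_trace(p, dose_schedule(), 600, grid_step = 5,
                         initial = x0)
  a <- objective_sq_deviation(coarse, tg)
  b <- objective_sq_deviation(fine, tg)
  expect_lt(abs(a - b) / b, 0.01)
})

test_that("combined objective composes the weighted criteria", {
  p <- test_patient()
  ev <- pkpd_evaluator(p, 600)
  tg <- target_from_patient(p)
  sch <- dose_schedule(c(0, 180), c(200, 150))
  tr <- ev(sch)
  spec_dose <- objective_spec(w_dose = 1, w_range = 0, w_threshold = 0)
  expect_equal(combined_objective(sch, ev, spec_dose, tg), 350)
  spec_mix <- objective_spec(w_dose = 2, w_dev = 0.5, w_range = 1,
                             w_threshold = 0)
  expect_equal(combined_objective(sch, ev, spec_mix, tg),
               2 * 350 + 0.5 * objective_sq_deviation(tr, tg) +
                 objective_outside_range(tr, tg))
  # an in-range trace scores zero on the range criterion
  flat_ev <- function(s) state_trace(seq(0, 300, 10), rep(tg$theta, 31))
  expect_equal(combined_objective(sch, flat_ev,
                                  objective_spec(w_range = 1,
                                                 w_threshold = 0), tg), 0)
  expect_error(objective_spec(w_dose = 0, w_range = 0, w_threshold = 0),
               "not all zero")
})
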