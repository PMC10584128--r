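coarse_problem <- function(p, day_length = 960, hard = TRUE) {
  ev <- pkpd_evaluator(p, day_length)
  tg <- target_from_patient(p)
  make_problem(ev, tg, constraints_from_numbers(1:4, time_step = 30), NULL,
               day_length, dose_step = 50, maint_max = 300, fill_day = TRUE,
               obj = objective_spec(w_range = 1, w_threshold = 1,
                                    threshold_mode = if (hard) "hard"
                                    else "penalty"))
}

test_that("exhaustive search equals an independent reversed-loop enumeration", {
  p <- test_patient()
  ev <- pkpd_evaluator(p, 960)
  tg <- target_from_patient(p)
  ex <- exhaustive_search(ev, tg, 960, dose_step = 50, interval_step = 30)
  # independent enumeration, loops in reversed order, plain which.min
  best <- Inf
  for (dn in rev(seq(0, 300, 50))) {
    for (dm in rev(seq(0, 400, 50))) {
      for (dt in rev(seq(90, 475, 30))) {
        nd <- floor(950 / dt) + 1
        sch <- schedule_from_intervals(0, rep(dt, nd - 1),
                                       c(dm, rep(dn, nd - 1)))
        tr <- ev(sch)
        if (!pdsched:::threshold_ok(tr, tg, 0)) next
        best <- min(best, objective_outside_range(tr, tg))
      }
    }
  }
  expect_equal(ex$score, best, tolerance = 1e-12)
  expect_true(ex$feasible)
})

test_that("a one-candidate grid returns that candidate", {
  p <- test_patient()
  ev <- pkpd_evaluator(p, 960)
  tg <- target_from_patient(p)
  ex <- exhaustive_search(ev, tg, 960, n_doses = 8, dose_step = 100,
                          interval_step = 500, morning_max = 100,
                          maint_max = 100, min_interval = 120)
  # interval grid = {120}; doses in {0, 100}
  expect_lte(ex$n_evaluated, 4)
  if (ex$feasible) expect_equal(n_doses(ex$schedule), 8)
})

test_that("an empty feasible grid is reported explicitly", {
  p <- test_patient()
  ev <- pkpd_evaluator(p, 960)
  tg <- target_from_patient(p)
  expect_warning(
    ex <- exhaustive_search(ev, tg, 960, dose_step = 5, interval_step = 30,
                            morning_max = 5, maint_max = 5),
    "no schedule")
  expect_false(ex$feasible)
  expect_true(is.infinite(ex$score))
})

test_that("GA and DE find the exhaustive optimum on a coarse grid", {
  pop <- test_population()
  pats <- sample_patients(pop, 3, seed = 33)
  for (i in seq_along(pats)) {
    p <- pats[[i]]
    ev <- pkpd_evaluator(p, 960)
    tg <- target_from_patient(p)
    ex <- exhaustive_search(ev, tg, 960, dose_step = 50, interval_step = 30)
    prob <- coarse_problem(p)
    ga <- optimize_ga(prob, pop_size = 200, generations = 100,
                      seed = 500 + i)
    de <- optimize_de(prob, pop_size = 30, generations = 40, seed = 600 + i)
    expect_equal(ga$score, ex$score, tolerance = 1e-9)
    expect_equal(de$score, ex$score, tolerance = 1e-9)
  }
})

test_that("optimizer results always satisfy bounds and constraints", {
  p <- test_patient()
  prob <- coarse_problem(p, hard = FALSE)
  for (seed in 1:3) {
    for (res in list(optimize_ga(prob, pop_size = 40, generations = 15,
                                 seed = seed),
                     optimize_de(prob, pop_size = 20, generations = 15,
                                 seed = seed, polish = FALSE))) {
      expect_true(all(res$vector >= prob$lower - 1e-9))
      expect_true(all(res$vector <= prob$upper + 1e-9))
      lat <- prob$lattice > 0
      expect_true(all(abs((res$vector[lat] - prob$lower[lat]) %%
                            prob$lattice[lat]) < 1e-9))
      sch <- res$schedule
      expect_equal(sch$times[1], 0)
      if (n_doses(sch) > 2) {
        expect_lt(diff(range(diff(sch$times))), 1e-9)
        expect_lt(diff(range(sch$sizes[-1])), 1e-9)
      }
    }
  }
})

test_that("optimizers are deterministic under a seed", {
  p <- test_patient()
  prob <- coarse_problem(p)
  a <- optimize_ga(prob, pop_size = 30, generations = 10, seed = 9)
  b <- optimize_ga(prob, pop_size = 30, generations = 10, seed = 9)
  expect_identical(a, b)
  d1 <- optimize_de(prob, pop_size = 20, generations = 10, seed = 9)
  d2 <- optimize_de(prob, pop_size = 20, generations = 10, seed = 9)
  expect_identical(d1, d2)
  expect_error(optimize_de(prob, pop_size = 2, generations = 5), "exceed 2")
  expect_error(optimize_ga(prob, pop_size = 2, generations = 5), "exceed 2")
})

test_that("degenerate DE operators leave the population invariant", {
  p <- test_patient()
  prob <- coarse_problem(p, hard = FALSE)
  res <- optimize_de(prob, pop_size = 10, generations = 10, cxpb = 0,
                     F = 0, seed = 3, polish = FALSE)
  set.seed(3)
  init_pop <- t(vapply(1:10, function(i)
    stats::runif(prob$dim, prob$lower, prob$upper), numeric(prob$dim)))
  init_best <- min(apply(init_pop, 1, function(v)
    prob$objective(prob$snap(v))))
  expect_equal(res$score, init_best, tolerance = 1e-12)
})

test_that("DE solves a quadratic self-test in the encoded space", {
  # separable quadratic over the 3-variable fully-constrained encoding;
  # analytic minimum at the lattice point closest to the continuous one
  con <- constraints_from_numbers(1:4)
  target <- target_spec(1, 0.5, 1.5, 0.3)
  prob <- make_problem(function(s) state_trace(seq(0, 300, 10), rep(1, 31)),
                       target, con, 4, 960, dose_step = 5,
                       obj = objective_spec())
  center <- c(130, 205, 105)
  prob$objective <- function(v) sum((v - center)^2)
  res <- optimize_de(prob, pop_size = 30, generations = 80, seed = 4)
  expect_equal(res$vector, c(130, 205, 105), tolerance = 1e-9)
  expect_lt(res$score, 1e-3)
})

test_that("relaxing constraints never worsens the warm-started objective", {
  pop <- test_population()
  pats <- sample_patients(pop, 2, seed = 77)
  rex <- relaxation_experiment(pats, seed = 5,
                               de_con = list(pop_size = 20, generations = 30),
                               de_rel = list(pop_size = 30, generations = 40))
  expect_true(all(rex$results$decrease_pct >= -1e-9))
  expect_true(all(rex$results$score_relaxed <=
                    rex$results$score_constrained + 1e-9))
})
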