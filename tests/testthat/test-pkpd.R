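test_that("effect law hits its closed-form anchors", {
  p <- test_patient()
  expect_equal(effect_from_concentration(0, p), p$BASE)
  expect_equal(effect_from_concentration(p$EC50, p), p$BASE + p$EMAX / 2)
  p2 <- test_patient(gamma = 2)
  expect_equal(effect_from_concentration(1e6 * p2$EC50, p2),
               p2$BASE + p2$EMAX, tolerance = 1e-6)
  expect_error(effect_from_concentration(-0.1, p), "non-negative|>= 0")
})

test_that("derivatives match direct substitution and steady state", {
  p <- test_patient()
  zero <- c(a0 = 0, a1 = 0, a2 = 0, ce = 0)
  p0 <- test_patient(Rsyn = 0)
  expect_equal(unname(pkpd_derivatives(zero, p0)), rep(0, 4))
  ss <- steady_state(p)
  expect_equal(unname(pkpd_derivatives(ss, p)), rep(0, 4),
               tolerance = 1e-12)
  D <- 100
  d <- pkpd_derivatives(c(a0 = D, a1 = 0, a2 = 0, ce = 0), p)
  expect_equal(d[["a0"]], -p$ka * D)
  expect_equal(d[["a1"]], p$BIO * p$ka * D + p$Rsyn)
})

test_that("no-dose simulation from steady state is constant", {
  p <- test_patient()
  tr <- simulate_trace(p, dose_schedule(), day_length = 960)
  s0 <- effect_from_concentration(p$Rsyn / p$CL, p)
  expect_lt(max(abs(tr$values - s0)), 1e-6)
  expect_equal(length(tr$values), 96)
})

test_that("absorption compartment follows the closed-form decay", {
  p <- test_patient(Rsyn = 0)
  D <- 250
  comp <- simulate_compartments(p, dose_schedule(0, D), day_length = 480,
                                initial = c(0, 0, 0, 0))
  tt <- seq(0, 470, by = 10)
  # the trace value at t = 0 is recorded before the bolus; afterwards the
  # depot follows a0(t) = D exp(-ka t)
  expect_equal(unname(comp[1, "a0"]), 0)
  expected <- D * exp(-p$ka * tt[-1])
  rel <- abs(comp[-1, "a0"] - expected) / expected
  expect_lt(max(rel), 1e-6)
})

test_that("exact stepping agrees with adaptive ODE integration", {
  p <- test_patient()
  sch <- dose_schedule(c(0, 180, 400), c(200, 100, 150))
  a <- simulate_trace(p, sch, 600, method = "exact")
  b <- simulate_trace(p, sch, 600, method = "ode")
  expect_lt(max(abs(a$values - b$values)), 1e-6)
})

test_that("simulation is deterministic and respects effect bounds", {
  p <- test_patient()
  sch <- dose_schedule(c(0, 120, 300, 500), c(300, 150, 400, 50))
  a <- simulate_trace(p, sch, 840)
  b <- simulate_trace(p, sch, 840)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= p$BASE - 1e-12))
  expect_true(all(a$values <= p$BASE + p$EMAX + 1e-12))
  expect_true(all(a$values >= -3 & a$values <= 3))
})

test_that("increasing a dose never decreases later concentrations", {
  p <- test_patient()
  for (amount in c(50, 100, 200)) {
    lo <- simulate_compartments(p, dose_schedule(c(0, 200), c(100, amount)),
                                day_length = 700)
    hi <- simulate_compartments(p, dose_schedule(c(0, 200),
                                                 c(100, amount + 100)),
                                day_length = 700)
    expect_true(all(hi[, "ce"] >= lo[, "ce"] - 1e-12))
  }
})

test_that("dose events outside the day or off the grid are rejected", {
  p <- test_patient()
  expect_error(simulate_trace(p, dose_schedule(1000, 100), 960), "within")
  expect_error(simulate_trace(p, dose_schedule(15, 100), 960), "grid")
  expect_error(simulate_trace(p, dose_schedule(0, 100), 955), "divide")
})
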