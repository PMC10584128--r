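test_that("degenerate population returns the means; draws respect bounds", {
  pop <- test_population()
  zero_pop <- population_model(pop$means, diag(0, 12), pop$clip_bounds)
  p <- sample_patient(zero_pop, seed = 5)
  expect_equal(unlist(p)[names(pop$means)], pop$means, tolerance = 1e-12)

  pats <- sample_patients(pop, 25, seed = 7)
  for (p in pats) {
    v <- unlist(p)[colnames(pop$clip_bounds)]
    expect_true(all(v >= pop$clip_bounds[1, ] - 1e-12))
    expect_true(all(v <= pop$clip_bounds[2, ] + 1e-12))
    expect_lte(p$BASE + p$EMAX, 3 + 1e-9)
  }
})

test_that("patient sampling is reproducible under a seed", {
  pop <- test_population()
  a <- sample_patients(pop, 5, seed = 42)
  b <- sample_patients(pop, 5, seed = 42)
  expect_identical(a, b)
})

test_that("non-PSD covariance is rejected", {
  pop <- test_population()
  bad <- diag(12); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(population_model(pop$means, bad, pop$clip_bounds),
               "positive semi-definite")
})

test_that("a 16-hour day yields 95 predicted states after the initial one", {
  p <- test_patient()
  cfg <- day_gen_config(wake_length_range = c(960, 960))
  day <- generate_day(p, cfg, seed = 2)
  expect_equal(length(day$trace$values) - 1, 95)
})

test_that("generated days respect gaps, grid alignment and effect bounds", {
  p <- test_patient()
  cfg <- day_gen_config()
  for (s in 1:8) {
    day <- generate_day(p, cfg, seed = s)
    sch <- day$schedule
    expect_gte(n_doses(sch), cfg$dose_count_range[1])
    expect_lte(n_doses(sch), cfg$dose_count_range[2])
    expect_equal(sch$times[1], 0)  # first dose at wake
    if (n_doses(sch) > 1)
      expect_true(all(diff(sch$times) >= cfg$min_interdose_gap))
    expect_true(all(sch$times %% cfg$grid_step == 0))
    expect_true(all(sch$sizes %in% cfg$dose_size_choices))
    expect_true(all(day$trace$values >= p$BASE - 1e-9 &
                    day$trace$values <= p$BASE + p$EMAX + 1e-9))
  }
})

test_that("zero dose count gives the no-dose simulation", {
  p <- test_patient()
  cfg <- day_gen_config(dose_count_range = c(0, 0),
                        wake_length_range = c(840, 840))
  day <- generate_day(p, cfg, seed = 1)
  expect_equal(n_doses(day$schedule), 0)
  ref <- simulate_trace(p, dose_schedule(), 840)
  expect_equal(day$trace$values, ref$values)
})

test_that("infeasible dose counts are reported", {
  p <- test_patient()
  cfg <- day_gen_config(wake_length_range = c(840, 840),
                        dose_count_range = c(12, 12))
  expect_error(generate_day(p, cfg, seed = 1), "infeasible")
})

test_that("day generation is deterministic under a seed", {
  p <- test_patient()
  a <- generate_day(p, seed = 9)
  b <- generate_day(p, seed = 9)
  expect_identical(a, b)
})

test_that("dataset CSV round trip is lossless", {
  pop <- test_population()
  cohort <- generate_cohort(pop, n_patients = 2, n_days = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset(cohort$days, path)
  back <- read_dataset(path)
  expect_equal(length(back), length(cohort$days))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$schedule$times, cohort$days[[i]]$schedule$times)
    expect_equal(back[[i]]$schedule$sizes, cohort$days[[i]]$schedule$sizes)
    expect_equal(back[[i]]$trace$values, cohort$days[[i]]$trace$values,
                 tolerance = 1e-12)
  }
})

test_that("empty dataset writes a header-only file", {
  path <- tempfile(fileext = ".csv")
  write_dataset(list(), path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 0)
  expect_equal(names(df),
               c("patient_id", "day_id", "time_min", "trs", "dose_mg"))
})

test_that("malformed dataset CSV errors name the problem", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,day_id,time_min", "1,1,0"), path)
  expect_error(read_dataset(path), "missing column")
  writeLines(c("patient_id,day_id,time_min,trs,dose_mg",
               "1,1,0,-1.5,0", "1,1,10,,0"), path)
  expect_error(read_dataset(path), "row")
})

test_that("the default cohort layout yields 150 day records", {
  # 50 patients x 3 days; day generation itself is cheap, so generate the
  # full layout but verify only the record count and ids
  pop <- test_population()
  cohort <- generate_cohort(pop, n_patients = 50, n_days = 3, seed = 1)
  expect_equal(length(cohort$days), 150)
  expect_equal(length(cohort$patients), 50)
})
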