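test_that("checkpointed best validation loss is non-increasing", {
  days <- lapply(1:10, function(i) linear_day(i, T = 30))
  fit <- train_general(days, impulse_model_config(lstm_units = 4,
                                                  hidden_sizes = c(8, 8)),
                       train_config(max_epochs = 15, patience = 14, seed = 3))
  best_so_far <- cummin(fit$history$val_loss)
  expect_true(all(diff(best_so_far) <= 1e-12))
  expect_lte(fit$best_val_loss, min(fit$history$val_loss) + 1e-12)
})

test_that("a linear dose-response system is learned almost perfectly", {
  days <- lapply(1:30, function(i) linear_day(i))
  fit <- train_general(days, impulse_model_config(lstm_units = 8,
                                                  hidden_sizes = c(32, 32)),
                       train_config(max_epochs = 500, patience = 60,
                                    seed = 2))
  ev <- evaluate_model(fit$model, days[fit$split$validation])
  expect_gt(ev$r2, 0.99)
})

test_that("training halts by epoch patience+1 when the loss cannot improve", {
  # constant traces with difference targets: a zero-weight model is exact
  # from the first epoch, so validation never improves after epoch 1
  days <- lapply(1:6, function(i) {
    list(schedule = dose_schedule(),
         trace = state_trace(seq(0, 200, 10), rep(-1, 21)))
  })
  cfg <- impulse_model_config(lstm_units = 3, hidden_sizes = c(4, 4),
                              target_mode = "difference")
  init <- init_model(cfg, seed = 1)
  init$params <- lapply(init$params, function(p) p * 0)
  fit <- train_general(days, cfg,
                       train_config(max_epochs = 50, patience = 5, seed = 1),
                       init = init)
  expect_lte(nrow(fit$history), 6)  # 1 improving epoch + patience
  expect_equal(fit$best_val_loss, 0, tolerance = 1e-20)
})

test_that("training requires at least two days", {
  expect_error(train_general(list(linear_day(1)), impulse_model_config(),
                             train_config()),
               "at least 2")
})

test_that("transfer learning freezes the LSTM and never regresses", {
  days <- lapply(1:12, function(i) linear_day(i, T = 40))
  gen <- train_general(days, impulse_model_config(lstm_units = 4,
                                                  hidden_sizes = c(16, 16)),
                       train_config(max_epochs = 60, patience = 15, seed = 4))
  pdays <- lapply(100:102, function(i) linear_day(i, T = 40, decay = 0.88))
  fit <- transfer_fit(gen$model, pdays,
                      transfer_config(max_epochs = 40, patience = 25,
                                      batch_size = 1, seed = 5))
  for (nm in c("Wx", "Wh", "b"))
    expect_identical(fit$model$params[[nm]], gen$model$params[[nm]])
  pre <- pdsched:::rollout_core(
    gen$model, pdsched:::make_batch(pdays[3], gen$model$cfg, 40))$loss
  expect_lte(fit$best_val_loss, pre + 1e-12)
  expect_error(transfer_fit(gen$model, pdays[1:2], transfer_config()),
               "exactly 3")
})

test_that("history-model transfer retrains every layer", {
  days <- lapply(1:8, function(i) linear_day(i, T = 30))
  gen <- train_general(days, history_model_config(hidden_sizes = c(8, 8)),
                       train_config(max_epochs = 30, patience = 10, seed = 6))
  pdays <- lapply(200:202, function(i) linear_day(i, T = 30, decay = 0.85))
  fit <- transfer_fit(gen$model, pdays,
                      transfer_config(max_epochs = 20, patience = 19,
                                      batch_size = 1, seed = 7))
  expect_false(identical(fit$model$params$W1, gen$model$params$W1))
})

test_that("model checkpoints survive a JSON round trip", {
  m <- mechanical_model(impulse_model_config(lstm_units = 4,
                                             hidden_sizes = c(8, 8)))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$params, m$params, tolerance = 1e-15)
  expect_equal(unclass(m2$norm), unclass(m$norm), tolerance = 1e-15)
  expect_equal(model_id(m2$cfg), model_id(m$cfg))
  tr1 <- rollout_predict(m, -1, dose_schedule(0, 100), 10)
  tr2 <- rollout_predict(m2, -1, dose_schedule(0, 100), 10)
  expect_equal(tr1$values, tr2$values, tolerance = 1e-12)
})

test_that("architecture identifiers parse and print consistently", {
  ids <- c("H-128,128-diff", "H-32,32-tanh", "H-64,64", "I-(8)64,64",
           "I-(16)16,16-diff", "I-(32)32,32-tanh")
  for (id in ids) expect_equal(model_id(model_from_id(id)), id)
  cfg <- model_from_id("H-32,32, tanh")
  expect_true(cfg$tanh_output)
  expect_error(model_from_id("X-1,2"), "unknown architecture")
})
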