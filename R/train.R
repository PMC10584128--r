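#' Training configuration
#'
#' Defaults follow the two training regimes used by the package: general
#' (population) training runs for up to 300 epochs with early-stopping
#' patience 10; patient-specific transfer runs for up to 100 epochs with
#' patience 25. Optimization is Adam at learning rate 0.001 with the best
#' model on the validation split checkpointed after every epoch.
#'
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param learning_rate Adam learning rate.
#' @param split_fraction fraction of days used for training (general fit).
#' @param batch_size minibatch size in days.
#' @param checkpoint_best return the best-on-validation weights.
#' @param grad_clip global gradient-norm clip.
#' @param seed integer seed for the split, weight draw and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 300, patience = 10,
                         learning_rate = 0.001, split_fraction = 0.8,
                         batch_size = 32, checkpoint_best = TRUE,
                         grad_clip = 5, seed = 1) {
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 split_fraction = split_fraction,
                 batch_size = as.integer(batch_size),
                 checkpoint_best = isTRUE(checkpoint_best),
                 grad_clip = grad_clip, seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @export
transfer_config <- function(max_epochs = 100, patience = 25, ...) {
  train_config(max_epochs = max_epochs, patience = patience, ...)
}

day_steps <- function(day) length(day$trace$times) - 1L

# Teacher-forced feature matrix over the training days (true previous
# states paired with the rollout dose features); used only to fit the
# input/target normalizer.
teacher_features <- function(days, cfg, T_steps, grid_step = 10) {
  batch <- make_batch(days, cfg, T_steps, grid_step)
  Xs <- list(); ys <- list()
  for (b in seq_along(days)) {
    s <- days[[b]]$trace$values
    prev <- s[seq_len(T_steps)]
    if (cfg$type == "history") {
      n <- cfg$n_prev_states
      Xp <- sapply(seq_len(n), function(l) s[pmax(seq_len(T_steps) - l + 1, 1)])
      Xs[[b]] <- cbind(matrix(Xp, T_steps, n), matrix(batch$dose[, b, ],
                                                      T_steps, 2 * cfg$k_prev_doses))
    } else {
      Xs[[b]] <- cbind(prev, batch$dose[, b])
    }
    ys[[b]] <- if (cfg$target_mode == "difference")
      batch$targets[, b] - prev else batch$targets[, b]
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

# shared epoch loop; `trainable` names the parameter arrays that receive
# updates (others stay frozen).
fit_rollout <- function(model, train_days, val_days, cfg,
                        trainable = names(model$params),
                        grid_step = 10) {
  T_train <- min(vapply(train_days, day_steps, integer(1)))
  T_val <- min(vapply(val_days, day_steps, integer(1)))
  val_batch <- make_batch(val_days, model$cfg, T_val, grid_step)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  wait <- 0L
  n_train <- length(train_days)
  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- sample(n_train)
    ep_loss <- 0; n_mb <- 0
    for (start in seq(1, n_train, by = cfg$batch_size)) {
      idx <- order_idx[start:min(start + cfg$batch_size - 1, n_train)]
      batch <- make_batch(train_days[idx], model$cfg, T_train, grid_step)
      res <- rollout_core(model, batch, want_grads = TRUE)
      grads <- res$grads
      for (nm in setdiff(names(grads), trainable)) grads[[nm]] <- NULL
      grads <- clip_grads(grads, cfg$grad_clip)
      upd <- adam_step(model$params, grads, opt, lr = cfg$learning_rate)
      model$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + res$loss; n_mb <- n_mb + 1
    }
    val_loss <- rollout_core(model, val_batch)$loss
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_mb,
                                         val_loss = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = model$params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (cfg$checkpoint_best) model$params <- best$params
  model$trained <- TRUE
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_loss = best$loss)
}

#' Train the general (population) response model
#'
#' Each day is one training sample: the initial state and the medicine
#' schedule are the inputs and the remaining grid states the targets. Days
#' are split randomly into training and validation sets (80/20 by
#' default), all days are truncated to the length of the shortest day, the
#' normalizer is fitted on the training split, and the model is trained by
#' whole-day rollout with the MSE over the entire predicted day as loss.
#' The best-on-validation weights are checkpointed and early stopping
#' halts training after `patience` epochs without improvement.
#'
#' @param days list of day records (`schedule` + `trace`), e.g. from
#'   [generate_cohort()].
#' @param model_cfg a [history_model_config()] or [impulse_model_config()].
#' @param cfg a [train_config()].
#' @param init optional `response_model` to warm-start from.
#' @param grid_step sampling step in minutes.
#' @return List with `model`, `history` (per-epoch losses), `split`
#'   (train/validation day indices), `best_epoch`, `best_val_loss`.
#' @export
train_general <- function(days, model_cfg, cfg = train_config(),
                          init = NULL, grid_step = 10) {
  if (length(days) < 2) stop("need at least 2 days to train")
  set.seed(cfg$seed)
  n <- length(days)
  n_train <- max(1L, min(n - 1L, round(cfg$split_fraction * n)))
  train_idx <- sort(sample(n, n_train))
  val_idx <- setdiff(seq_len(n), train_idx)
  model <- if (is.null(init)) init_model(model_cfg, seed = cfg$seed) else init
  T_min <- min(vapply(days[train_idx], day_steps, integer(1)))
  tf <- teacher_features(days[train_idx], model_cfg, T_min, grid_step)
  model$norm <- fit_normalizer(tf$X, tf$y,
                               standardize_target = !model_cfg$tanh_output)
  fit <- fit_rollout(model, days[train_idx], days[val_idx], cfg,
                     grid_step = grid_step)
  fit$split <- list(train = train_idx, validation = val_idx)
  fit
}

#' Transfer-fit a general model to one patient
#'
#' Retrains a trained general model on a single patient's 3 observed days
#' (2 training days, the last day for validation). For the history model
#' every layer is retrained; for the impulse model the LSTM weights are
#' frozen and only the fully connected layers are updated. The
#' best-on-validation weights are kept (patience 25, at most 100 epochs by
#' default).
#'
#' @param general a trained `response_model`.
#' @param patient_days list of exactly 3 day records for one patient.
#' @param cfg a [transfer_config()].
#' @param grid_step sampling step in minutes.
#' @return As [train_general()].
#' @export
transfer_fit <- function(general, patient_days, cfg = transfer_config(),
                         grid_step = 10) {
  if (!isTRUE(general$trained)) stop("general model must be trained first")
  if (length(patient_days) != 3)
    stop("transfer learning expects exactly 3 patient days (2 train, 1 validation)")
  set.seed(cfg$seed)
  trainable <- if (general$cfg$type == "impulse")
    c("W1", "b1", "W2", "b2", "W3", "b3") else names(general$params)
  fit <- fit_rollout(general, patient_days[1:2], patient_days[3], cfg,
                     trainable = trainable, grid_step = grid_step)
  fit$split <- list(train = 1:2, validation = 3L)
  fit
}

#' Prediction metrics for a set of days
#'
#' Rolls the model out over each day and pools all predicted states to
#' compute the mean squared error, mean absolute error and coefficient of
#' determination `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param model a trained `response_model`.
#' @param days list of day records.
#' @param grid_step sampling step in minutes.
#' @return List with `mse`, `mae`, `r2`, `n`.
#' @export
evaluate_model <- function(model, days, grid_step = 10) {
  if (!length(days)) stop("need at least one day to evaluate")
  y <- c(); yhat <- c()
  for (d in days) {
    T <- day_steps(d)
    pr <- rollout_predict(model, d$trace$values[1], d$schedule, T, grid_step)
    y <- c(y, d$trace$values[2:(T + 1)])
    yhat <- c(yhat, pr$values[2:(T + 1)])
  }
  metrics_report(y, yhat)
}

#' @rdname evaluate_model
#' @param y,yhat true and predicted values.
#' @export
metrics_report <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("constant targets: R^2 is undefined")
    NaN
  } else 1 - sum((y - yhat)^2) / sst
  list(mse = mean((y - yhat)^2), mae = mean(abs(y - yhat)), r2 = r2,
       n = length(y))
}

#' Paired Wilcoxon signed-rank comparison of model losses
#'
#' Compares two equal-length paired samples of per-trial losses with the
#' Wilcoxon signed-rank test. With `alternative = "greater"` a small
#' p-value supports that the first sample is stochastically greater
#' (i.e. the second model is better).
#'
#' @param losses_a,losses_b paired per-trial losses (length >= 5).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return List with `p_value`, `statistic` and `degenerate` (TRUE when
#'   all paired differences are zero, in which case the statistic is
#'   undefined and `p_value` is `NA`).
#' @export
compare_models_wilcoxon <- function(losses_a, losses_b,
                                    alternative = c("greater", "less",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(losses_a) != length(losses_b))
    stop("paired samples must have equal length")
  if (length(losses_a) < 5) stop("need at least 5 pairs")
  if (all(losses_a == losses_b)) {
    warning("all paired differences are zero: signed-rank statistic undefined")
    return(list(p_value = NA_real_, statistic = NA_real_, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(losses_a, losses_b,
                                            paired = TRUE,
                                            alternative = alternative))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       degenerate = FALSE)
}
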