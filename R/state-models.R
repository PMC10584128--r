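#' History (feed-forward) response-model configuration
#'
#' The history model is a multilayer perceptron that predicts the next TRS
#' state from the `n` previous states and the `k` most recent medication
#' doses (each dose contributes a time-since-dose / dose-size pair), so
#' the input width is `n + 2k`.
#'
#' @param n_prev_states number of previous states in the input (default 1).
#' @param k_prev_doses number of recent doses in the input (default 2).
#' @param hidden_sizes widths of the two dense hidden layers.
#' @param target_mode `"next_state"` predicts the state itself;
#'   `"difference"` predicts the change from the previous state.
#' @param tanh_output pass the output through `3 * tanh(.)` so every
#'   prediction lies inside the TRS scale `[-3, 3]`.
#' @return An object of class `history_config`.
#' @export
history_model_config <- function(n_prev_states = 1, k_prev_doses = 2,
                                 hidden_sizes = c(64, 64),
                                 target_mode = c("next_state", "difference"),
                                 tanh_output = FALSE) {
  stopifnot(n_prev_states >= 1, k_prev_doses >= 1, length(hidden_sizes) == 2)
  structure(list(type = "history",
                 n_prev_states = as.integer(n_prev_states),
                 k_prev_doses = as.integer(k_prev_doses),
                 hidden_sizes = as.integer(hidden_sizes),
                 target_mode = match.arg(target_mode),
                 tanh_output = isTRUE(tanh_output)),
            class = "history_config")
}

#' Impulse (LSTM) response-model configuration
#'
#' The impulse model feeds an LSTM layer exactly two values per step - the
#' previous state and the dose administered at the step - followed by two
#' dense hidden layers. The recurrent cell state carries the full
#' medication history.
#'
#' @param lstm_units number of LSTM units.
#' @inheritParams history_model_config
#' @return An object of class `impulse_config`.
#' @export
impulse_model_config <- function(lstm_units = 8, hidden_sizes = c(64, 64),
                                 target_mode = c("next_state", "difference"),
                                 tanh_output = FALSE) {
  stopifnot(lstm_units >= 1, length(hidden_sizes) == 2)
  structure(list(type = "impulse",
                 lstm_units = as.integer(lstm_units),
                 hidden_sizes = as.integer(hidden_sizes),
                 target_mode = match.arg(target_mode),
                 tanh_output = isTRUE(tanh_output)),
            class = "impulse_config")
}

#' Parse an architecture identifier
#'
#' Accepts the compact identifiers used in the model-selection tables,
#' e.g. `"H-128,128-diff"`, `"H-32,32-tanh"` (also written
#' `"H-32,32, tanh"`), `"I-(8)64,64"`, `"I-(16)16,16-diff"`.
#'
#' @param id identifier string.
#' @return A `history_config` or `impulse_config`.
#' @export
model_from_id <- function(id) {
  m <- regmatches(id, regexec(
    "^([HI])-(?:\\((\\d+)\\))?(\\d+),(\\d+)(-diff|-tanh|, ?tanh)?$", id))[[1]]
  if (!length(m)) stop(sprintf("unknown architecture identifier '%s'", id))
  suffix <- m[6]
  target <- if (identical(suffix, "-diff")) "difference" else "next_state"
  tanh_out <- grepl("tanh", suffix)
  if (m[2] == "H") {
    history_model_config(hidden_sizes = as.integer(c(m[4], m[5])),
                         target_mode = target, tanh_output = tanh_out)
  } else {
    if (m[3] == "") stop("impulse identifier must give the LSTM units, e.g. I-(8)64,64")
    impulse_model_config(lstm_units = as.integer(m[3]),
                         hidden_sizes = as.integer(c(m[4], m[5])),
                         target_mode = target, tanh_output = tanh_out)
  }
}

#' Canonical identifier of a model configuration
#' @param cfg a model configuration.
#' @export
model_id <- function(cfg) {
  suffix <- if (cfg$target_mode == "difference") "-diff"
  else if (cfg$tanh_output) "-tanh" else ""
  if (cfg$type == "history")
    sprintf("H-%d,%d%s", cfg$hidden_sizes[1], cfg$hidden_sizes[2], suffix)
  else
    sprintf("I-(%d)%d,%d%s", cfg$lstm_units, cfg$hidden_sizes[1],
            cfg$hidden_sizes[2], suffix)
}

history_input_width <- function(cfg) cfg$n_prev_states + 2L * cfg$k_prev_doses

#' Initialize an untrained response model
#'
#' Dense kernels use Glorot-uniform initialization; the LSTM input kernel
#' is Glorot, the recurrent kernel orthogonal, and the forget-gate bias
#' starts at 1.
#'
#' @param cfg a `history_config` or `impulse_config`.
#' @param seed integer seed for the weight draw.
#' @return An object of class `response_model`.
#' @export
init_model <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- cfg$hidden_sizes
  if (cfg$type == "history") {
    m <- history_input_width(cfg)
    params <- list(W1 = glorot_uniform(m, h[1]), b1 = numeric(h[1]),
                   W2 = glorot_uniform(h[1], h[2]), b2 = numeric(h[2]),
                   W3 = glorot_uniform(h[2], 1), b3 = numeric(1))
  } else {
    u <- cfg$lstm_units
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- 1  # forget gate bias
    params <- list(Wx = glorot_uniform(2, 4 * u),
                   Wh = orthogonal_init(u, 4 * u),
                   b = b,
                   W1 = glorot_uniform(u, h[1]), b1 = numeric(h[1]),
                   W2 = glorot_uniform(h[1], h[2]), b2 = numeric(h[2]),
                   W3 = glorot_uniform(h[2], 1), b3 = numeric(1))
  }
  structure(list(cfg = cfg, params = params, norm = NULL, trained = FALSE),
            class = c(paste0(cfg$type, "_model"), "response_model"))
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Response model %s (%s)\n", model_id(x$cfg),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# --- normalization --------------------------------------------------------

#' Feature / target normalizer
#'
#' Per-feature mean and standard deviation computed on the training split;
#' applying and then inverting the transform is the identity. For
#' `tanh_output` models the target is left on the raw TRS scale (the
#' `3 * tanh` head already produces TRS values).
#'
#' @param X training feature matrix.
#' @param y training target vector.
#' @param standardize_target FALSE for `tanh_output` models.
#' @return An object of class `normalizer`.
#' @export
fit_normalizer <- function(X, y, standardize_target = TRUE) {
  x_sd <- apply(X, 2, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  structure(list(x_mean = colMeans(X), x_sd = x_sd,
                 y_mean = if (standardize_target) mean(y) else 0,
                 y_sd = if (standardize_target) y_sd else 1),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param norm a `normalizer`.
#' @export
norm_transform <- function(norm, X) {
  sweep(sweep(X, 2, norm$x_mean, "-"), 2, norm$x_sd, "/")
}

#' @rdname fit_normalizer
#' @export
norm_inverse <- function(norm, X) {
  sweep(sweep(X, 2, norm$x_sd, "*"), 2, norm$x_mean, "+")
}

# --- feature builders -----------------------------------------------------

#' Build history-model features for one day
#'
#' One row per grid time `t`: the `n` previous states (the initial state
#' is replicated into missing slots at the start of the day), then for
#' each of the `k` most recent doses taken at or before `t` a
#' (time-since-dose, dose-size) pair, zeros when fewer than `k` doses have
#' been taken. The time since a dose is 0 at the step where the dose
#' occurs. The target of row `t` is the state at `t` (or its change from
#' the previous state in difference mode).
#'
#' @param trace a [state_trace()].
#' @param schedule a [dose_schedule()] on the same grid (non-aligned times
#'   are rounded to the nearest grid point).
#' @param cfg a [history_model_config()].
#' @return List with `features` (matrix), `targets`, `times`.
#' @export
build_history_features <- function(trace, schedule, cfg = history_model_config()) {
  gs <- trace_step(trace)
  schedule <- align_schedule(schedule, gs)
  if (length(schedule$times) && max(schedule$times) > max(trace$times))
    stop("schedule and trace grids are inconsistent")
  N <- length(trace$times)
  n <- cfg$n_prev_states; k <- cfg$k_prev_doses
  X <- matrix(0, N, n + 2 * k)
  y <- numeric(N)
  for (r in seq_len(N)) {
    t_r <- trace$times[r]
    for (l in seq_len(n)) X[r, l] <- trace$values[max(r - l, 1)]
    taken <- which(schedule$times <= t_r + 1e-9)
    if (length(taken)) {
      taken <- taken[order(schedule$times[taken], decreasing = TRUE)]
      taken <- taken[seq_len(min(k, length(taken)))]
      for (j in seq_along(taken)) {
        X[r, n + 2 * j - 1] <- t_r - schedule$times[taken[j]]
        X[r, n + 2 * j] <- schedule$sizes[taken[j]]
      }
    }
    y[r] <- if (cfg$target_mode == "difference")
      trace$values[r] - trace$values[max(r - 1, 1)] else trace$values[r]
  }
  state_cols <- paste0("prev_state_", seq_len(n))
  dose_cols <- as.vector(rbind(paste0("time_since_dose_", seq_len(k)),
                               paste0("dose_size_", seq_len(k))))
  colnames(X) <- c(state_cols, dose_cols)
  list(features = X, targets = y, times = trace$times)
}

#' Build impulse-model features for one day
#'
#' One row per grid time `t`: the previous state and the dose administered
#' at `t` (0 when no medicine was taken). Dose times that fall between
#' grid points are rounded to the nearest grid point.
#'
#' @inheritParams build_history_features
#' @return List with `features` (N x 2 matrix), `targets`, `times`.
#' @export
build_impulse_features <- function(trace, schedule,
                                   cfg = impulse_model_config()) {
  gs <- trace_step(trace)
  schedule <- align_schedule(schedule, gs)
  N <- length(trace$times)
  dose <- numeric(N)
  if (length(schedule$times)) {
    idx <- match(schedule$times, trace$times)
    ok <- !is.na(idx)
    dose[idx[ok]] <- dose[idx[ok]] + schedule$sizes[ok]
  }
  prev <- trace$values[pmax(seq_len(N) - 1, 1)]
  y <- if (cfg$target_mode == "difference") trace$values - prev
  else trace$values
  X <- cbind(prev_state = prev, dose = dose)
  list(features = X, targets = y, times = trace$times)
}
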