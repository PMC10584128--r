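# Whole-day rollout engine: closed-loop forward prediction (each predicted
# state is fed back as the next input's previous state) and
# backpropagation through time, batched over days. The loss is the MSE
# over the entire predicted day, never per-step teacher forcing.

identity_normalizer <- function(width) {
  structure(list(x_mean = numeric(width), x_sd = rep(1, width),
                 y_mean = 0, y_sd = 1), class = "normalizer")
}

# dose features for prediction steps at the given times
hist_dose_feats <- function(schedule, times, k) {
  X <- matrix(0, length(times), 2 * k)
  if (!length(schedule$times)) return(X)
  for (r in seq_along(times)) {
    taken <- which(schedule$times <= times[r] + 1e-9)
    if (length(taken)) {
      taken <- taken[order(schedule$times[taken], decreasing = TRUE)]
      taken <- taken[seq_len(min(k, length(taken)))]
      for (j in seq_along(taken)) {
        X[r, 2 * j - 1] <- times[r] - schedule$times[taken[j]]
        X[r, 2 * j] <- schedule$sizes[taken[j]]
      }
    }
  }
  X
}

# Doses taken before the first prediction step (a dose at wake, t = 0) are
# attributed to the first step: a bolus at t influences the state one grid
# step later, which is exactly when the model first sees it.
impulse_dose_vec <- function(schedule, times, clamp_first = TRUE) {
  d <- numeric(length(times))
  tt <- schedule$times
  if (clamp_first && length(tt)) tt <- pmax(tt, times[1])
  for (j in seq_along(tt)) {
    i <- which(abs(times - tt[j]) < 1e-9)
    if (length(i)) d[i] <- d[i] + schedule$sizes[j]
  }
  d
}

# Assemble a batched rollout problem from day records, truncated to T steps.
make_batch <- function(days, cfg, T_steps, grid_step = 10) {
  B <- length(days)
  init <- vapply(days, function(d) d$trace$values[1], numeric(1))
  targets <- matrix(0, T_steps, B)
  times <- seq_len(T_steps) * grid_step
  if (cfg$type == "history") {
    dose <- array(0, c(T_steps, B, 2 * cfg$k_prev_doses))
    for (b in seq_len(B)) {
      dose[, b, ] <- hist_dose_feats(align_schedule(days[[b]]$schedule, grid_step),
                                     times, cfg$k_prev_doses)
      targets[, b] <- days[[b]]$trace$values[2:(T_steps + 1)]
    }
  } else {
    dose <- matrix(0, T_steps, B)
    for (b in seq_len(B)) {
      dose[, b] <- impulse_dose_vec(align_schedule(days[[b]]$schedule, grid_step),
                                    times)
      targets[, b] <- days[[b]]$trace$values[2:(T_steps + 1)]
    }
  }
  list(init = init, targets = targets, dose = dose, T = T_steps, B = B,
       grid_step = grid_step)
}

head_layers <- function(params) {
  list(list(W = params$W1, b = params$b1),
       list(W = params$W2, b = params$b2),
       list(W = params$W3, b = params$b3))
}

# map network output z (B x 1) to raw state; returns s and cache for backward
map_output <- function(z, s_prev, cfg, norm) {
  if (cfg$tanh_output) {
    tz <- tanh(z)
    v <- 3 * tz
    dz <- 3 * (1 - tz^2)
  } else {
    v <- norm$y_mean + norm$y_sd * z
    dz <- rep(norm$y_sd, length(z))
  }
  s <- if (cfg$target_mode == "difference") s_prev + c(v) else c(v)
  if (cfg$tanh_output) {
    mask <- (s > -3) & (s < 3)
    s <- pmin(3, pmax(-3, s))
  } else mask <- rep(TRUE, length(s))
  list(s = s, dz = c(dz), mask = mask)
}

# ---- history model -------------------------------------------------------

history_rollout <- function(params, cfg, norm, batch, want_grads = FALSE) {
  T <- batch$T; B <- batch$B
  n <- cfg$n_prev_states; k <- cfg$k_prev_doses; m <- n + 2 * k
  layers <- head_layers(params)
  # normalize exogenous dose features once
  doseN <- batch$dose
  for (j in seq_len(2 * k)) {
    doseN[, , j] <- (batch$dose[, , j] - norm$x_mean[n + j]) / norm$x_sd[n + j]
  }
  prev <- matrix(batch$init, B, n)      # raw previous states, col 1 most recent
  pred <- matrix(0, T, B)
  caches <- if (want_grads) vector("list", T) else NULL
  for (t in seq_len(T)) {
    xs <- sweep(sweep(prev, 2, norm$x_mean[seq_len(n)], "-"),
                2, norm$x_sd[seq_len(n)], "/")
    x <- cbind(xs, matrix(doseN[t, , ], B, 2 * k))
    fw <- dense_forward(layers, x)
    mo <- map_output(fw$out, prev[, 1], cfg, norm)
    pred[t, ] <- mo$s
    if (want_grads) caches[[t]] <- list(fw = fw, dz = mo$dz, mask = mo$mask)
    prev <- cbind(mo$s, prev[, seq_len(max(n - 1, 0)), drop = FALSE])
  }
  out <- list(pred = pred)
  if (!is.null(batch$targets))
    out$loss <- mean((pred - batch$targets)^2)
  if (!want_grads) return(out)

  grads <- zero_like(params)
  dS <- 2 * (pred - batch$targets) / (T * B)
  for (t in rev(seq_len(T))) {
    ds <- dS[t, ] * caches[[t]]$mask
    if (cfg$target_mode == "difference" && t > 1) dS[t - 1, ] <- dS[t - 1, ] + ds
    dz <- ds * caches[[t]]$dz
    bw <- dense_backward(layers, caches[[t]]$fw, matrix(dz, B, 1))
    grads$W1 <- grads$W1 + bw$grads[[1]]$W; grads$b1 <- grads$b1 + bw$grads[[1]]$b
    grads$W2 <- grads$W2 + bw$grads[[2]]$W; grads$b2 <- grads$b2 + bw$grads[[2]]$b
    grads$W3 <- grads$W3 + bw$grads[[3]]$W; grads$b3 <- grads$b3 + bw$grads[[3]]$b
    for (l in seq_len(n)) {
      if (t - l >= 1) dS[t - l, ] <- dS[t - l, ] + bw$dX[, l] / norm$x_sd[l]
    }
  }
  out$grads <- grads
  out
}

# ---- impulse model -------------------------------------------------------

impulse_rollout <- function(params, cfg, norm, batch, want_grads = FALSE,
                            return_cells = FALSE) {
  T <- batch$T; B <- batch$B; u <- cfg$lstm_units
  layers <- head_layers(params)
  doseN <- (batch$dose - norm$x_mean[2]) / norm$x_sd[2]
  h <- matrix(0, B, u); cc <- matrix(0, B, u)
  s_prev <- batch$init
  pred <- matrix(0, T, B)
  caches <- if (want_grads) vector("list", T) else NULL
  iu <- seq_len(u); fu <- u + iu; gu <- 2 * u + iu; ou <- 3 * u + iu
  for (t in seq_len(T)) {
    x <- cbind((s_prev - norm$x_mean[1]) / norm$x_sd[1], doseN[t, ])
    Z <- x %*% params$Wx + h %*% params$Wh
    Z <- sweep(Z, 2, params$b, "+")
    gi <- sigmoid(Z[, iu, drop = FALSE])
    gf <- sigmoid(Z[, fu, drop = FALSE])
    gg <- tanh(Z[, gu, drop = FALSE])
    go <- sigmoid(Z[, ou, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    fw <- dense_forward(layers, h)
    mo <- map_output(fw$out, s_prev, cfg, norm)
    pred[t, ] <- mo$s
    if (want_grads)
      caches[[t]] <- list(x = x, gi = gi, gf = gf, gg = gg, go = go,
                          c_prev = c_prev, tc = tc, h_prev = h_prev,
                          fw = fw, dz = mo$dz, mask = mo$mask)
    s_prev <- mo$s
  }
  out <- list(pred = pred)
  if (return_cells) out$cells <- list(h = h, c = cc)
  if (!is.null(batch$targets))
    out$loss <- mean((pred - batch$targets)^2)
  if (!want_grads) return(out)

  grads <- zero_like(params)
  dS <- 2 * (pred - batch$targets) / (T * B)
  dh_carry <- matrix(0, B, u); dc_carry <- matrix(0, B, u)
  for (t in rev(seq_len(T))) {
    ca <- caches[[t]]
    ds <- dS[t, ] * ca$mask
    if (cfg$target_mode == "difference") {
      if (t > 1) dS[t - 1, ] <- dS[t - 1, ] + ds
    }
    dz <- ds * ca$dz
    bw <- dense_backward(layers, ca$fw, matrix(dz, B, 1))
    grads$W1 <- grads$W1 + bw$grads[[1]]$W; grads$b1 <- grads$b1 + bw$grads[[1]]$b
    grads$W2 <- grads$W2 + bw$grads[[2]]$W; grads$b2 <- grads$b2 + bw$grads[[2]]$b
    grads$W3 <- grads$W3 + bw$grads[[3]]$W; grads$b3 <- grads$b3 + bw$grads[[3]]$b
    dh <- bw$dX + dh_carry
    dc <- dc_carry + dh * ca$go * (1 - ca$tc^2)
    d_go <- dh * ca$tc * ca$go * (1 - ca$go)
    d_gf <- dc * ca$c_prev * ca$gf * (1 - ca$gf)
    d_gi <- dc * ca$gg * ca$gi * (1 - ca$gi)
    d_gg <- dc * ca$gi * (1 - ca$gg^2)
    dZ <- cbind(d_gi, d_gf, d_gg, d_go)
    grads$Wx <- grads$Wx + crossprod(ca$x, dZ)
    grads$Wh <- grads$Wh + crossprod(ca$h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dh_carry <- dZ %*% t(params$Wh)
    dc_carry <- dc * ca$gf
    dx <- dZ %*% t(params$Wx)
    if (t > 1) dS[t - 1, ] <- dS[t - 1, ] + dx[, 1] / norm$x_sd[1]
  }
  out$grads <- grads
  out
}

rollout_core <- function(model, batch, want_grads = FALSE, ...) {
  if (model$cfg$type == "history")
    history_rollout(model$params, model$cfg, model$norm, batch, want_grads)
  else
    impulse_rollout(model$params, model$cfg, model$norm, batch, want_grads, ...)
}

#' Predict a whole day by closed-loop rollout
#'
#' Starting from the initial (wake) state, predicts `n_steps` grid states
#' iteratively, feeding each predicted state back as the next step's
#' previous-state input. The impulse model starts from a zero recurrent
#' cell state; in difference mode each prediction is the previous state
#' plus the model output; `tanh_output` models never emit a state outside
#' `[-3, 3]`.
#'
#' @param model a trained `response_model`.
#' @param initial_state TRS score at wake.
#' @param schedule a [dose_schedule()].
#' @param n_steps number of grid states to predict.
#' @param grid_step grid step in minutes.
#' @return A [state_trace()] of `n_steps + 1` values starting with the
#'   initial state.
#' @export
rollout_predict <- function(model, initial_state, schedule, n_steps,
                            grid_step = 10) {
  if (!isTRUE(model$trained) || is.null(model$norm))
    stop("model must be trained before rollout prediction")
  if (n_steps < 0) stop("n_steps must be >= 0")
  times <- seq(0, n_steps * grid_step, by = grid_step)
  if (n_steps == 0)
    return(state_trace(0, initial_state, grid_step))
  day <- list(schedule = schedule,
              trace = state_trace(times, rep(initial_state, n_steps + 1)))
  batch <- make_batch(list(day), model$cfg, n_steps, grid_step)
  batch$targets <- NULL
  res <- rollout_core(model, batch)
  state_trace(times, c(initial_state, res$pred[, 1]),
              (n_steps + 1) * grid_step)
}

#' Reference rollout implementation
#'
#' A deliberately naive scalar, layer-by-layer re-implementation of the
#' rollout forward pass, kept as an independent arithmetic path to verify
#' the fast vectorized engine.
#'
#' @inheritParams rollout_predict
#' @export
rollout_predict_reference <- function(model, initial_state, schedule, n_steps,
                                      grid_step = 10) {
  cfg <- model$cfg; norm <- model$norm; P <- model$params
  if (n_steps == 0) return(state_trace(0, initial_state, grid_step))
  times <- seq_len(n_steps) * grid_step
  relu_s <- function(v) ifelse(v > 0, v, 0)
  dense_s <- function(v) {
    h1 <- relu_s(as.numeric(v %*% P$W1) + P$b1)
    h2 <- relu_s(as.numeric(h1 %*% P$W2) + P$b2)
    as.numeric(h2 %*% P$W3) + P$b3
  }
  finish <- function(z, sp) {
    v <- if (cfg$tanh_output) 3 * tanh(z) else norm$y_mean + norm$y_sd * z
    s <- if (cfg$target_mode == "difference") sp + v else v
    if (cfg$tanh_output) s <- min(3, max(-3, s))
    s
  }
  out <- numeric(n_steps)
  sp <- initial_state
  if (cfg$type == "history") {
    k <- cfg$k_prev_doses; n <- cfg$n_prev_states
    df <- hist_dose_feats(align_schedule(schedule, grid_step), times, k)
    prevs <- rep(initial_state, n)
    for (t in seq_len(n_steps)) {
      x_raw <- c(prevs, df[t, ])
      x <- (x_raw - norm$x_mean) / norm$x_sd
      out[t] <- finish(dense_s(x), prevs[1])
      prevs <- c(out[t], prevs)[seq_len(n)]
    }
  } else {
    u <- cfg$lstm_units
    dv <- impulse_dose_vec(align_schedule(schedule, grid_step), times)
    h <- numeric(u); cc <- numeric(u)
    for (t in seq_len(n_steps)) {
      x <- c((sp - norm$x_mean[1]) / norm$x_sd[1],
             (dv[t] - norm$x_mean[2]) / norm$x_sd[2])
      zg <- numeric(4 * u)
      for (j in seq_len(4 * u))
        zg[j] <- sum(x * P$Wx[, j]) + sum(h * P$Wh[, j]) + P$b[j]
      gi <- 1 / (1 + exp(-zg[seq_len(u)]))
      gf <- 1 / (1 + exp(-zg[u + seq_len(u)]))
      gg <- tanh(zg[2 * u + seq_len(u)])
      go <- 1 / (1 + exp(-zg[3 * u + seq_len(u)]))
      cc <- gf * cc + gi * gg
      h <- go * tanh(cc)
      out[t] <- finish(dense_s(h), sp)
      sp <- out[t]
    }
  }
  state_trace(c(0, times), c(initial_state, out), (n_steps + 1) * grid_step)
}
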