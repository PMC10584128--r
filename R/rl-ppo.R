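#' PPO agent configuration
#'
#' On-policy actor-critic training with a clipped surrogate objective.
#' Defaults mirror common PPO practice (rollout buffer of 2048 steps,
#' 10 optimization epochs on 64-sample minibatches, discount 0.99, GAE
#' 0.95, clip 0.2, Adam at 3e-4); the policy and value networks are
#' separate multilayer perceptrons with two rectified hidden layers —
#' 400 neurons each for a 5 mg dose step, 200 for 50 mg. A callback
#' every `check_period` timesteps evaluates the deterministic policy and
#' stops training when no improvement is seen for two consecutive
#' checks.
#'
#' @param hidden sizes of the two policy/value hidden layers.
#' @param total_timesteps training budget in environment steps.
#' @param n_steps rollout buffer size per update.
#' @param batch_size minibatch size.
#' @param n_epochs optimization epochs per update.
#' @param gamma discount factor.
#' @param gae_lambda generalized-advantage-estimation factor.
#' @param clip_range PPO clipping parameter.
#' @param learning_rate Adam learning rate.
#' @param ent_coef entropy-bonus coefficient.
#' @param vf_coef value-loss coefficient.
#' @param max_grad_norm global gradient clip.
#' @param check_period evaluation / early-stop period in timesteps.
#' @param eval_episodes evaluation episodes per check.
#' @param seed integer seed.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(hidden = c(200, 200), total_timesteps = 500000,
                         n_steps = 2048, batch_size = 64, n_epochs = 10,
                         gamma = 0.99, gae_lambda = 0.95, clip_range = 0.2,
                         learning_rate = 3e-4, ent_coef = 0, vf_coef = 0.5,
                         max_grad_norm = 0.5, check_period = 50000,
                         eval_episodes = 5, seed = 1) {
  if (total_timesteps %% check_period != 0)
    stop("total_timesteps must be a multiple of check_period")
  structure(as.list(environment()), class = "agent_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# running mean/var observation normalizer (Welford over batches)
rms_init <- function(dim) list(mean = numeric(dim), var = rep(1, dim),
                               count = 1e-4)
rms_update <- function(rms, X) {
  bm <- colMeans(X); bv <- apply(X, 2, stats::var) * (nrow(X) - 1) / nrow(X)
  bv[is.na(bv)] <- 0
  bc <- nrow(X)
  delta <- bm - rms$mean
  tot <- rms$count + bc
  new_mean <- rms$mean + delta * bc / tot
  m_a <- rms$var * rms$count
  m_b <- bv * bc
  m2 <- m_a + m_b + delta^2 * rms$count * bc / tot
  list(mean = new_mean, var = m2 / tot, count = tot)
}
rms_apply <- function(rms, obs) {
  pmin(pmax((obs - rms$mean) / sqrt(rms$var + 1e-8), -10), 10)
}

#' Sample or choose an action from a trained policy
#'
#' @param policy a policy object from [train_agent()].
#' @param obs raw observation vector.
#' @param deterministic take the argmax action instead of sampling.
#' @export
policy_action <- function(policy, obs, deterministic = TRUE) {
  x <- matrix(rms_apply(policy$rms, obs), 1)
  logits <- dense_forward(policy$actor, x)$out
  if (deterministic) which.max(logits[1, ]) - 1L
  else sample(length(logits), 1, prob = softmax_rows(logits)[1, ]) - 1L
}

eval_policy <- function(policy, env, episodes = 5) {
  rewards <- numeric(episodes)
  for (ep in seq_len(episodes)) {
    res <- env_reset(env)
    total <- 0
    repeat {
      a <- policy_action(policy, res$observation, deterministic = TRUE)
      st <- env_step(env, a)
      total <- total + st$reward
      res <- st
      if (st$terminated || st$truncated) break
    }
    rewards[ep] <- total
  }
  mean(rewards)
}

#' Train a PPO dosing agent
#'
#' Trains a discrete-action policy on a [dosing_env()] with the clipped
#' surrogate objective, generalized advantage estimation and periodic
#' deterministic evaluation with early stopping; the best evaluated
#' policy snapshot is returned.
#'
#' @param env a [dosing_env()].
#' @param cfg an [agent_config()].
#' @param verbose print evaluation progress.
#' @return A policy object (class `ppo_policy`) with elements `actor`,
#'   `critic`, `rms`, `history` and `best_eval`.
#' @export
train_agent <- function(env, cfg = agent_config(), verbose = FALSE) {
  set.seed(cfg$seed)
  obs0 <- env_reset(env)$observation
  obs_dim <- length(obs0)
  n_act <- env$cfg$n_actions
  actor <- dense_init(c(obs_dim, cfg$hidden, n_act))
  critic <- dense_init(c(obs_dim, cfg$hidden, 1))
  opt_a <- adam_init(flatten_layers(actor))
  opt_c <- adam_init(flatten_layers(critic))
  rms <- rms_init(obs_dim)
  history <- data.frame(timestep = integer(0), eval_reward = numeric(0))
  best <- list(reward = -Inf, actor = actor, critic = critic, rms = rms)
  checks_without_improvement <- 0L
  steps_done <- 0L
  obs <- obs0
  ep_done <- FALSE
  while (steps_done < cfg$total_timesteps) {
    n <- min(cfg$n_steps, cfg$total_timesteps - steps_done)
    OBS <- matrix(0, n, obs_dim)
    ACT <- integer(n); LOGP <- numeric(n); REW <- numeric(n)
    DONE <- logical(n); BOOT <- numeric(n); VAL <- numeric(n)
    raw_obs <- matrix(0, n, obs_dim)
    for (t in seq_len(n)) {
      raw_obs[t, ] <- obs
      x <- matrix(rms_apply(rms, obs), 1)
      logits <- dense_forward(actor, x)$out
      p <- softmax_rows(logits)[1, ]
      a <- sample(n_act, 1, prob = p) - 1L
      v <- dense_forward(critic, x)$out[1, 1]
      st <- env_step(env, a)
      OBS[t, ] <- x; ACT[t] <- a; LOGP[t] <- log(p[a + 1]); VAL[t] <- v
      REW[t] <- st$reward
      DONE[t] <- st$terminated || st$truncated
      if (st$truncated) {
        # time-limit truncation: bootstrap with the value of the final
        # observation (termination by exceeding the state cap does not)
        xf <- matrix(rms_apply(rms, st$observation), 1)
        BOOT[t] <- dense_forward(critic, xf)$out[1, 1]
      }
      obs <- st$observation
      if (DONE[t]) obs <- env_reset(env)$observation
    }
    rms <- rms_update(rms, raw_obs)
    last_val <- dense_forward(critic, matrix(rms_apply(rms, obs), 1))$out[1, 1]
    ADV <- numeric(n)
    gae <- 0
    for (t in rev(seq_len(n))) {
      if (DONE[t]) {
        delta <- REW[t] + cfg$gamma * BOOT[t] - VAL[t]
        gae <- delta
      } else {
        next_val <- if (t == n) last_val else VAL[t + 1]
        delta <- REW[t] + cfg$gamma * next_val - VAL[t]
        gae <- delta + cfg$gamma * cfg$gae_lambda * gae
      }
      ADV[t] <- gae
    }
    RET <- ADV + VAL
    for (epoch in seq_len(cfg$n_epochs)) {
      idx_all <- sample(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        mb <- idx_all[start:min(start + cfg$batch_size - 1, n)]
        nb <- length(mb)
        X <- OBS[mb, , drop = FALSE]
        adv <- ADV[mb]
        adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
        fa <- dense_forward(actor, X)
        P <- softmax_rows(fa$out)
        lp_new <- log(P[cbind(seq_len(nb), ACT[mb] + 1)])
        ratio <- exp(lp_new - LOGP[mb])
        surr1 <- ratio * adv
        surr2 <- pmin(pmax(ratio, 1 - cfg$clip_range),
                      1 + cfg$clip_range) * adv
        active <- surr1 <= surr2
        coef <- -adv * ratio * active / nb
        dlogits <- matrix(0, nb, n_act)
        dlogits[cbind(seq_len(nb), ACT[mb] + 1)] <- coef
        dlogits <- dlogits - P * coef
        if (cfg$ent_coef > 0) {
          lp_all <- log(pmax(P, 1e-12))
          H <- -rowSums(P * lp_all)
          dlogits <- dlogits + cfg$ent_coef * P * (lp_all + H) / nb
        }
        ga <- dense_backward(actor, fa, dlogits)$grads
        fa_g <- flatten_grads(ga)
        fa_g <- clip_grads(fa_g, cfg$max_grad_norm)
        upd <- adam_step(flatten_layers(actor), fa_g, opt_a,
                         lr = cfg$learning_rate)
        actor <- unflatten_layers(upd$params, actor)
        opt_a <- upd$state
        fc <- dense_forward(critic, X)
        dv <- matrix(2 * cfg$vf_coef * (fc$out[, 1] - RET[mb]) / nb)
        gc <- dense_backward(critic, fc, dv)$grads
        fc_g <- clip_grads(flatten_grads(gc), cfg$max_grad_norm)
        updc <- adam_step(flatten_layers(critic), fc_g, opt_c,
                          lr = cfg$learning_rate)
        critic <- unflatten_layers(updc$params, critic)
        opt_c <- updc$state
      }
    }
    prev_done <- steps_done
    steps_done <- steps_done + n
    if (steps_done %/% cfg$check_period > prev_done %/% cfg$check_period ||
        steps_done >= cfg$total_timesteps) {
      pol <- structure(list(actor = actor, critic = critic, rms = rms),
                       class = "ppo_policy")
      er <- eval_policy(pol, env, cfg$eval_episodes)
      history <- rbind(history, data.frame(timestep = steps_done,
                                           eval_reward = er))
      if (verbose)
        message(sprintf("timestep %d: eval reward %.2f", steps_done, er))
      if (er > best$reward + 1e-9) {
        best <- list(reward = er, actor = actor, critic = critic, rms = rms)
        checks_without_improvement <- 0L
      } else {
        checks_without_improvement <- checks_without_improvement + 1L
        if (checks_without_improvement >= 2L) break
      }
      obs <- env_reset(env)$observation
    }
  }
  structure(list(actor = best$actor, critic = best$critic, rms = best$rms,
                 history = history, best_eval = best$reward,
                 cfg = cfg), class = "ppo_policy")
}

flatten_layers <- function(layers) {
  out <- list()
  for (l in seq_along(layers)) {
    out[[paste0("W", l)]] <- layers[[l]]$W
    out[[paste0("b", l)]] <- layers[[l]]$b
  }
  out
}

unflatten_layers <- function(flat, layers) {
  for (l in seq_along(layers)) {
    layers[[l]]$W <- flat[[paste0("W", l)]]
    layers[[l]]$b <- flat[[paste0("b", l)]]
  }
  layers
}

flatten_grads <- function(grads) {
  out <- list()
  for (l in seq_along(grads)) {
    out[[paste0("W", l)]] <- grads[[l]]$W
    out[[paste0("b", l)]] <- grads[[l]]$b
  }
  out
}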