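# Minimal neural-network primitives used by the response models and the
# PPO agent: Glorot/orthogonal initialization, a dense-stack forward /
# backward pass, and an Adam optimizer over flat parameter lists.

glorot_uniform <- function(nin, nout) {
  limit <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -limit, limit), nin, nout)
}

orthogonal_init <- function(nin, nout) {
  a <- matrix(stats::rnorm(max(nin, nout)^2), max(nin, nout))
  q <- qr.Q(qr(a))
  q[seq_len(nin), seq_len(nout), drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Dense stack: hidden layers ReLU, linear output. `sizes` includes input
# and output widths, e.g. c(4, 64, 64, 1).
dense_init <- function(sizes) {
  layers <- list()
  for (l in seq_len(length(sizes) - 1)) {
    layers[[l]] <- list(W = glorot_uniform(sizes[l], sizes[l + 1]),
                        b = numeric(sizes[l + 1]))
  }
  layers
}

dense_forward <- function(layers, X) {
  L <- length(layers)
  acts <- vector("list", L)  # post-activation inputs to each layer
  h <- X
  for (l in seq_len(L)) {
    acts[[l]] <- h
    z <- h %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    h <- if (l < L) pmax(z, 0) else z
  }
  list(out = h, acts = acts)
}

# dOut: gradient wrt the linear output. Returns per-layer grads and dX.
dense_backward <- function(layers, cache, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    inp <- cache$acts[[l]]
    if (l < L) {
      # recompute activation mask from the next layer's stored input
      mask <- cache$acts[[l + 1]] > 0
      d <- d * mask
    }
    grads[[l]] <- list(W = crossprod(inp, d), b = colSums(d))
    d <- d %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = d)
}

# --- Adam over flat named lists of arrays ---------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_grads <- function(grads, max_norm) {
  gn <- grad_global_norm(grads)
  if (is.finite(max_norm) && gn > max_norm && gn > 0)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
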