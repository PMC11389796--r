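# AdamW over flat named parameter lists, plus the Huber criterion used for
# regression training.

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay (applied directly to the weights, not the
# gradient), betas (0.9, 0.999) as training defaults.
adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                       eps = 1e-8, weight_decay = 0.01, skip_decay = character(0)) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gmat
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gmat * gmat
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !(nm %in% skip_decay)) {
      params[[nm]] <- params[[nm]] - lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# Huber loss and its derivative w.r.t. the prediction; delta = 1 balances
# MAE and RMSE behaviour around unit-scale residuals.
huber_loss <- function(pred, y, delta = 1) {
  r <- pred - y
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r * r, delta * (a - 0.5 * delta))
}

huber_grad <- function(pred, y, delta = 1) {
  pmax(pmin(pred - y, delta), -delta)
}

# elementwise sum of two flat grad lists (b may have fewer entries)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

grads_scale <- function(a, s) lapply(a, function(g) g * s)
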