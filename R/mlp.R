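## Compact multilayer perceptron trained by full-batch Adam with a
## reduce-on-plateau schedule and a masked mean-squared-error loss (rows
## with a missing label contribute zero gradient to that output head).
## Everything is plain matrix arithmetic, seeded and bitwise reproducible.

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.mlp_init <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l + 1] * dims[l], sd = sqrt(2 / dims[l])),
      dims[l + 1], dims[l])
    params[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  params
}

# forward pass; X is n x d.  Returns activations for backprop.
.mlp_forward <- function(params, X) {
  nl <- length(params) / 2
  A <- list(t(X))  # layers work on d x n
  Zs <- list()
  for (l in seq_len(nl)) {
    Z <- params[[paste0("W", l)]] %*% A[[l]] + params[[paste0("b", l)]]
    Zs[[l]] <- Z
    A[[l + 1]] <- if (l < nl) pmax(Z, 0) else Z  # ReLU hidden, linear out
  }
  list(A = A, Z = Zs, yhat = t(A[[nl + 1]]))
}

# masked MSE loss and gradient at the output (n x T matrices)
.masked_mse <- function(yhat, y, mask) {
  n_eff <- sum(mask)
  err <- (yhat - y) * mask
  list(loss = sum(err^2) / n_eff, dy = 2 * err / n_eff)
}

.mlp_backward <- function(params, fwd, dY) {
  nl <- length(params) / 2
  grads <- params
  delta <- t(dY)  # T x n
  for (l in nl:1) {
    grads[[paste0("W", l)]] <- delta %*% t(fwd$A[[l]])
    grads[[paste0("b", l)]] <- rowSums(delta)
    if (l > 1) {
      delta <- (t(params[[paste0("W", l)]]) %*% delta) * (fwd$Z[[l - 1]] > 0)
    }
  }
  grads
}

# shared trainer: full-batch Adam + plateau scheduler + early stopping.
# forward_fn(params, X) -> yhat (n x T); backward_fn(params, X, dY) -> grads
.train_loop <- function(params, forward_fn, backward_fn,
                        Xtr, Ytr, Mtr, Xval, Yval, Mval,
                        epochs, lr, plateau_factor = 0.5,
                        plateau_patience = 10, early_stop_patience = Inf,
                        min_lr = 1e-6) {
  state <- .adam_init(params)
  hist <- matrix(NA_real_, epochs, 2,
                 dimnames = list(NULL, c("train", "validation")))
  best <- Inf; best_params <- params; since_best <- 0L; since_lr <- 0L
  has_val <- nrow(Xval) > 0 && sum(Mval) > 0
  for (ep in seq_len(epochs)) {
    fw <- forward_fn(params, Xtr)
    tr <- .masked_mse(fw$yhat, Ytr, Mtr)
    grads <- backward_fn(params, fw, tr$dy)
    st <- .adam_step(params, grads, state, lr)
    params <- st$params; state <- st$state
    vloss <- if (has_val) {
      .masked_mse(forward_fn(params, Xval)$yhat, Yval, Mval)$loss
    } else tr$loss
    hist[ep, ] <- c(tr$loss, vloss)
    if (vloss < best - 1e-12) {
      best <- vloss; best_params <- params
      since_best <- 0L; since_lr <- 0L
    } else {
      since_best <- since_best + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= plateau_patience && lr > min_lr) {
        lr <- max(lr * plateau_factor, min_lr)
        since_lr <- 0L
      }
      if (since_best >= early_stop_patience) {
        hist <- hist[seq_len(ep), , drop = FALSE]
        break
      }
    }
  }
  list(params = best_params, history = hist, final_lr = lr)
}
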