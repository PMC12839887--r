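## Hybrid variational-quantum-circuit regressor: a two-layer classical
## encoder maps the 13 standardized features to 12 embedding angles, the
## 12-qubit circuit (angle embedding + 2 basic entangling layers of
## trainable RX rotations and a CNOT ring) is simulated exactly, the twelve
## Pauli-Z expectations feed an affine head, and the whole stack is trained
## end-to-end against the masked MSE loss.  Circuit gradients are exact
## adjoint-statevector gradients (they match finite differences to ~1e-8).

.vqc_init <- function(d_in, encoder_hidden, n_qubits, layers, d_out) {
  list(
    W1 = matrix(stats::rnorm(encoder_hidden * d_in, sd = sqrt(2 / d_in)),
                encoder_hidden, d_in),
    b1 = numeric(encoder_hidden),
    W2 = matrix(stats::rnorm(n_qubits * encoder_hidden,
                             sd = sqrt(1 / encoder_hidden)),
                n_qubits, encoder_hidden),
    b2 = numeric(n_qubits),
    theta = matrix(stats::rnorm(layers * n_qubits, sd = 0.1),
                   layers, n_qubits),
    Wh = matrix(0, d_out, n_qubits),
    bh = numeric(d_out))
}

# encoder + circuit + head forward.  X is n x d.  Caches per-sample
# intermediates for the backward pass.
.vqc_forward <- function(params, X) {
  n <- nrow(X)
  H1 <- pmax(params$W1 %*% t(X) + params$b1, 0)      # h x n
  ANG <- params$W2 %*% H1 + params$b2                # q x n
  nq <- nrow(ANG)
  Z <- matrix(0, n, nq)
  for (i in seq_len(n)) {
    Z[i, ] <- simulate_circuit(ANG[, i], params$theta)
  }
  yhat <- t(params$Wh %*% t(Z) + params$bh)
  list(yhat = yhat, H1 = H1, ANG = ANG, Z = Z, X = X)
}

.vqc_backward <- function(params, fw, dY) {
  n <- nrow(fw$X)
  grads <- lapply(params, function(p) p * 0)
  grads$Wh <- t(dY) %*% fw$Z
  grads$bh <- colSums(dY)
  dZ <- dY %*% params$Wh                      # n x q
  dANG <- matrix(0, nrow(fw$ANG), n)
  for (i in seq_len(n)) {
    if (all(dZ[i, ] == 0)) next  # fully masked row: no circuit pass needed
    cg <- .circuit_grad(fw$ANG[, i], params$theta, dZ[i, ])
    dANG[, i] <- cg$d_features
    grads$theta <- grads$theta + cg$d_params
  }
  grads$W2 <- dANG %*% t(fw$H1)
  grads$b2 <- rowSums(dANG)
  dH1 <- (t(params$W2) %*% dANG) * (fw$H1 > 0)
  grads$W1 <- dH1 %*% fw$X
  grads$b1 <- rowSums(dH1)
  grads
}

# deterministic least-squares warm start of the affine head: with the
# encoder and circuit at their initial values the head sees fixed features
# z, and the masked quadratic loss has a closed-form per-target minimizer.
.vqc_warm_start_head <- function(params, X, Y, M, ridge = 1e-6) {
  fw <- .vqc_forward(params, X)
  Zc <- cbind(1, fw$Z)
  for (t in seq_len(ncol(Y))) {
    rows <- which(M[, t])
    if (length(rows) < ncol(Zc)) next
    A <- Zc[rows, , drop = FALSE]
    co <- solve(crossprod(A) + ridge * diag(ncol(A)), crossprod(A, Y[rows, t]))
    params$bh[t] <- co[1]
    params$Wh[t, ] <- co[-1]
  }
  params
}
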