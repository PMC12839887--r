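# Independent numerical oracles used across the suite.

# dense 1-D radial quadrature for spherically symmetric integrands:
# Int f(r) 4 pi r^2 dr by the trapezoidal rule
radial_oracle <- function(f, rmax = 30, n = 1e5) {
  r <- seq(rmax / n, rmax, length.out = n)
  h <- r[2] - r[1]
  v <- f(r) * 4 * pi * r^2
  h * (sum(v) - 0.5 * (v[1] + v[n]))
}

# brute-force dense-unitary circuit oracle, built from explicit gate
# matrices and kronecker products (independent of the statevector engine).
# Convention: qubit q occupies bit (q-1), so it sits at kron position
# (n - q + 1) from the left.
dense_circuit <- function(features, params) {
  n <- length(features)
  embed1 <- function(g, q) {
    m <- g
    if (q < n) m <- kronecker(diag(2^(n - q)), m)
    if (q > 1) m <- kronecker(m, diag(2^(q - 1)))
    m
  }
  rx <- function(th) {
    matrix(c(cos(th / 2), -1i * sin(th / 2),
             -1i * sin(th / 2), cos(th / 2)), 2, 2)
  }
  P0 <- diag(c(1, 0)); P1 <- diag(c(0, 1))
  X <- matrix(c(0, 1, 1, 0), 2)
  U <- diag(2^n)
  for (q in seq_len(n)) U <- embed1(rx(features[q]), q) %*% U
  for (l in seq_len(nrow(params))) {
    for (q in seq_len(n)) U <- embed1(rx(params[l, q]), q) %*% U
    if (n > 1) {
      for (q in seq_len(n)) {
        t <- if (q == n) 1L else q + 1L
        U <- (embed1(P0, q) + embed1(P1, q) %*% embed1(X, t)) %*% U
      }
    }
  }
  psi <- U[, 1]
  vapply(seq_len(n), function(q) {
    s <- 1 - 2 * (bitwAnd(0:(2^n - 1), bitwShiftL(1L, q - 1L)) != 0L)
    Re(sum(s * Mod(psi)^2))
  }, 0)
}

# shared small grids (built once per test run)
grid_1atom_fine <- function() {
  build_molecular_grid(atoms("H", matrix(0, 1, 3)), 75L, 288L)
}
grid_1atom_coarse <- function() {
  build_molecular_grid(atoms("H", matrix(0, 1, 3)), 30L, 98L)
}
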