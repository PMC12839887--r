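## Exact statevector simulation of the variational circuit used by the
## hybrid regressor: per-qubit RX angle embedding, L "basic entangling"
## layers (trainable RX on every qubit followed by a ring of CNOTs), and
## Pauli-Z expectation readout on every qubit.  The gate kernels and the
## adjoint-mode differentiation (exact gradients of every rotation angle,
## embedding angles included, at ~3x the cost of one forward pass) live in
## compiled code (src/circuit.cpp).

#' Simulate the variational circuit
#'
#' Starts from |0...0>, applies `RX(features[q])` on every qubit, then for
#' each row of `params` a layer of trainable `RX` rotations followed by a
#' ring of CNOTs (control q, target q+1 mod n; omitted for a single qubit),
#' and returns the Pauli-Z expectation of every qubit.  Deterministic,
#' noiseless, exact statevector arithmetic.
#'
#' @param features numeric vector of embedding angles (one per qubit).
#' @param params numeric matrix, layers x qubits, of trainable angles (a
#'   vector is taken as one layer; `matrix(0, 0, n)` means no layer).
#' @return numeric vector of `<Z_q>` values in `[-1, 1]`.
#' @examples
#' simulate_circuit(rep(0, 3), matrix(0, 2, 3))  # all ones
#' simulate_circuit(pi, matrix(0, 0, 1))         # single qubit: cos(pi)
#' @export
simulate_circuit <- function(features, params) {
  features <- as.numeric(features)
  if (!all(is.finite(features))) stop("non-finite embedding angle")
  n <- length(features)
  if (n < 1 || n > 24) stop("qubit count out of range")
  if (is.null(dim(params))) {
    params <- if (length(params) == 0) matrix(0, 0, n) else
      matrix(params, ncol = n, byrow = TRUE)
  }
  if (nrow(params) > 0) {
    if (ncol(params) != n) stop("params must have one column per qubit")
    if (!all(is.finite(params))) stop("non-finite circuit parameter")
  }
  .cpp_circuit_z(features, params)
}

# adjoint-mode gradient; g = dLoss/d<Z_q>.  Returns z, dLoss/dfeatures,
# dLoss/dparams.
.circuit_grad <- function(features, params, g) {
  .cpp_circuit_adjoint(as.numeric(features), params, as.numeric(g))
}
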