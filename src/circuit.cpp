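// Statevector kernels for the variational circuit: RX angle embedding,
// L layers of trainable RX rotations + CNOT ring, Pauli-Z readout, and
// adjoint-mode differentiation of all rotation angles.  Qubit q occupies
// bit (q-1) of the state index (little-endian).  Amplitudes are kept as
// separate real/imaginary arrays and all gate arithmetic is written out in
// real components (a library complex multiply costs ~10x here).  The
// backward pass fuses, per rotation gate, the gradient accumulation and
// the un-application of the gate to the state and the adjoint vector.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct state_t {
  std::vector<double> re, im;
  explicit state_t(size_t dim) : re(dim, 0.0), im(dim, 0.0) {}
  size_t size() const { return re.size(); }
};

#define PAIR_LOOP(bit, dim, ...)                           \
  for (size_t base = 0; base < (dim); base += 2 * (bit)) { \
    for (size_t i = base; i < base + (bit); ++i) {         \
      const size_t j = i | (bit);                          \
      __VA_ARGS__                                          \
    }                                                      \
  }

// RX(theta) on the (a, b) pair: a' = c a - i s b, b' = c b - i s a
static inline void apply_rx(state_t &psi, int q, double theta) {
  const size_t bit = size_t(1) << (q - 1);
  const size_t dim = psi.size();
  const double c = std::cos(theta / 2.0), s = std::sin(theta / 2.0);
  PAIR_LOOP(bit, dim, {
    const double ar = psi.re[i], ai = psi.im[i];
    const double br = psi.re[j], bi = psi.im[j];
    psi.re[i] = c * ar + s * bi;
    psi.im[i] = c * ai - s * br;
    psi.re[j] = c * br + s * ai;
    psi.im[j] = c * bi - s * ar;
  })
}

static inline void apply_cnot(state_t &psi, int ctrl, int targ) {
  const size_t cb = size_t(1) << (ctrl - 1);
  const size_t tb = size_t(1) << (targ - 1);
  const size_t dim = psi.size();
  PAIR_LOOP(tb, dim, {
    if (i & cb) {
      std::swap(psi.re[i], psi.re[j]);
      std::swap(psi.im[i], psi.im[j]);
    }
  })
}

static void run_circuit(state_t &psi, const NumericVector &features,
                        const NumericMatrix &params) {
  const int n = features.size();
  const int L = params.nrow();
  for (int q = 1; q <= n; ++q) apply_rx(psi, q, features[q - 1]);
  for (int l = 0; l < L; ++l) {
    for (int q = 1; q <= n; ++q) apply_rx(psi, q, params(l, q - 1));
    if (n > 1) {
      for (int q = 1; q <= n; ++q) apply_cnot(psi, q, q == n ? 1 : q + 1);
    }
  }
}

static NumericVector z_expectations(const state_t &psi, int n) {
  NumericVector z(n);
  std::vector<double> acc(n, 0.0);
  const size_t dim = psi.size();
  for (size_t i = 0; i < dim; ++i) {
    const double p = psi.re[i] * psi.re[i] + psi.im[i] * psi.im[i];
    for (int q = 0; q < n; ++q) {
      acc[q] += (i & (size_t(1) << q)) ? -p : p;
    }
  }
  for (int q = 0; q < n; ++q) z[q] = acc[q];
  return z;
}

// [[Rcpp::export(name = ".cpp_circuit_z")]]
NumericVector cpp_circuit_z(NumericVector features, NumericMatrix params) {
  const int n = features.size();
  state_t psi(size_t(1) << n);
  psi.re[0] = 1.0;
  run_circuit(psi, features, params);
  return z_expectations(psi, n);
}

// gradient of the rotation gate whose output state psi currently is,
// fused with un-applying the gate (RX(-theta)) to psi and lam:
//   grad = 2 Re< lam | (-i/2) X_q | psi > = sum Im( conj(lam) (X psi) )
static inline double rx_grad_unapply(state_t &psi, state_t &lam, int q,
                                     double theta) {
  const size_t bit = size_t(1) << (q - 1);
  const size_t dim = psi.size();
  const double c = std::cos(theta / 2.0), s = std::sin(theta / 2.0);
  double acc = 0.0;
  PAIR_LOOP(bit, dim, {
    const double ar = psi.re[i], ai = psi.im[i];
    const double br = psi.re[j], bi = psi.im[j];
    const double lar = lam.re[i], lai = lam.im[i];
    const double lbr = lam.re[j], lbi = lam.im[j];
    // Im(conj(la) * b) + Im(conj(lb) * a)
    acc += lar * bi - lai * br + lbr * ai - lbi * ar;
    // RX(-theta): a' = c a + i s b, b' = c b + i s a
    psi.re[i] = c * ar - s * bi;
    psi.im[i] = c * ai + s * br;
    psi.re[j] = c * br - s * ai;
    psi.im[j] = c * bi + s * ar;
    lam.re[i] = c * lar - s * lbi;
    lam.im[i] = c * lai + s * lbr;
    lam.re[j] = c * lbr - s * lai;
    lam.im[j] = c * lbi + s * lar;
  })
  return acc;
}

static inline void cnot_unapply_both(state_t &psi, state_t &lam, int ctrl,
                                     int targ) {
  const size_t cb = size_t(1) << (ctrl - 1);
  const size_t tb = size_t(1) << (targ - 1);
  const size_t dim = psi.size();
  PAIR_LOOP(tb, dim, {
    if (i & cb) {
      std::swap(psi.re[i], psi.re[j]);
      std::swap(psi.im[i], psi.im[j]);
      std::swap(lam.re[i], lam.re[j]);
      std::swap(lam.im[i], lam.im[j]);
    }
  })
}

// adjoint differentiation: returns z, dLoss/dfeatures, dLoss/dparams for
// upstream gradient g = dLoss/d<Z_q>.
// [[Rcpp::export(name = ".cpp_circuit_adjoint")]]
List cpp_circuit_adjoint(NumericVector features, NumericMatrix params,
                         NumericVector g) {
  const int n = features.size();
  const int L = params.nrow();
  const size_t dim = size_t(1) << n;
  state_t psi(dim);
  psi.re[0] = 1.0;
  run_circuit(psi, features, params);
  NumericVector z = z_expectations(psi, n);

  // lambda = H_eff psi with diagonal H_eff = sum_q g_q Z_q
  state_t lam(dim);
  for (size_t i = 0; i < dim; ++i) {
    double d = 0.0;
    for (int q = 0; q < n; ++q) {
      d += (i & (size_t(1) << q)) ? -g[q] : g[q];
    }
    lam.re[i] = d * psi.re[i];
    lam.im[i] = d * psi.im[i];
  }

  NumericMatrix d_params(L, n);
  for (int l = L - 1; l >= 0; --l) {
    if (n > 1) {
      for (int q = n; q >= 1; --q) {
        cnot_unapply_both(psi, lam, q, q == n ? 1 : q + 1);
      }
    }
    for (int q = n; q >= 1; --q) {
      d_params(l, q - 1) = rx_grad_unapply(psi, lam, q, params(l, q - 1));
    }
  }
  NumericVector d_features(n);
  for (int q = n; q >= 1; --q) {
    d_features[q - 1] = rx_grad_unapply(psi, lam, q, features[q - 1]);
  }
  return List::create(Named("z") = z, Named("d_features") = d_features,
                      Named("d_params") = d_params);
}
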