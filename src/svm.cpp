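#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Linear soft-margin SVM solvers for binary problems, dense feature
// matrices. The bias term is handled by the caller through augmentation
// with a constant column, so every solver optimises over w alone.
//
// Solver names follow the regularisation/loss convention used for linear
// SVMs: 2R-2L = L2-regularised L2-loss (squared hinge), 2R-1L =
// L2-regularised L1-loss (hinge), 1R-2L = L1-regularised L2-loss.

namespace {

// Deterministic 32-bit xorshift PRNG: solver results must not depend on
// (or perturb) R's global RNG stream.
struct XorShift32 {
  uint32_t state;
  explicit XorShift32(uint32_t seed) : state(seed ? seed : 2463534242u) {}
  uint32_t next() {
    uint32_t x = state;
    x ^= x << 13; x ^= x >> 17; x ^= x << 5;
    state = x;
    return x;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint32_t>(n)); }
};

inline double dot_row(const NumericMatrix& X, int i, const std::vector<double>& w) {
  const int d = X.ncol(), n = X.nrow();
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += X[i + n * static_cast<R_xlen_t>(j)] * w[j];
  return s;
}

} // namespace

// Dual coordinate descent for L2-regularised hinge (L1-loss) and squared
// hinge (L2-loss) SVC. Follows the standard shrinking-free formulation:
// min_a 0.5 a' Qbar a - e' a, 0 <= a_i <= U, with Qbar = Q + D,
// D_ii = 0 (L1 loss, U = C) or 1/(2C) (L2 loss, U = inf).
// [[Rcpp::export(name = ".svm_l2r_dual")]]
NumericVector svm_l2r_dual(NumericMatrix X, NumericVector y, double C,
                           bool squared_loss, double tol, int max_iter,
                           int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qii(n);
  const double diag = squared_loss ? 0.5 / C : 0.0;
  const double U = squared_loss ? R_PosInf : C;

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      const double v = X[i + n * static_cast<R_xlen_t>(j)];
      s += v * v;
    }
    qii[i] = s + diag;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  XorShift32 rng(static_cast<uint32_t>(seed) + 1u);

  for (int iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle, seeded: deterministic for fixed inputs.
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);

    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      if (qii[i] <= 0) continue;  // all-zero row: alpha stays 0
      const double yi = y[i];
      const double G = yi * dot_row(X, i, w) - 1.0 + diag * alpha[i];

      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= U && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);

      if (std::fabs(PG) > 1e-12) {
        const double old = alpha[i];
        double a = old - G / qii[i];
        if (a < 0.0) a = 0.0;
        if (a > U) a = U;
        alpha[i] = a;
        const double delta = (a - old) * yi;
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j)
            w[j] += delta * X[i + n * static_cast<R_xlen_t>(j)];
        }
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}

// Coordinate descent with per-coordinate Newton step and backtracking line
// search for L1-regularised L2-loss SVC:
//   min_w |w|_1 + C * sum_i max(0, 1 - y_i w.x_i)^2
// [[Rcpp::export(name = ".svm_l1r_l2l")]]
NumericVector svm_l1r_l2l(NumericMatrix X, NumericVector y, double C,
                          double tol, int max_iter, int seed) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> w(d, 0.0), fx(n, 0.0);  // fx_i = w . x_i
  const double sigma = 0.01, beta = 0.5;
  XorShift32 rng(static_cast<uint32_t>(seed) + 7u);
  std::vector<int> order(d);
  for (int j = 0; j < d; ++j) order[j] = j;

  auto loss = [&](void) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const double m = 1.0 - y[i] * fx[i];
      if (m > 0) s += m * m;
    }
    return C * s;
  };

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int j = d - 1; j > 0; --j) std::swap(order[j], order[rng.below(j + 1)]);
    double max_step = 0.0;

    for (int k = 0; k < d; ++k) {
      const int j = order[k];
      double g = 0.0, h = 1e-12;
      for (int i = 0; i < n; ++i) {
        const double m = 1.0 - y[i] * fx[i];
        if (m > 0) {
          const double xij = X[i + n * static_cast<R_xlen_t>(j)];
          g += -2.0 * C * y[i] * xij * m;
          h += 2.0 * C * xij * xij;
        }
      }
      // Minimise |w_j + z| + g z + h z^2 / 2 in z (Newton direction).
      double z;
      if (g + 1.0 <= h * w[j])      z = -(g + 1.0) / h;
      else if (g - 1.0 >= h * w[j]) z = -(g - 1.0) / h;
      else                          z = -w[j];
      if (std::fabs(z) < 1e-14) continue;

      // Armijo backtracking on the true objective.
      const double L0 = loss();
      const double delta_lin = g * z + std::fabs(w[j] + z) - std::fabs(w[j]);
      double lambda = 1.0;
      for (int ls = 0; ls < 30; ++ls) {
        const double zl = lambda * z;
        double Lnew = 0.0;
        for (int i = 0; i < n; ++i) {
          const double m = 1.0 - y[i] * (fx[i] + zl * X[i + n * static_cast<R_xlen_t>(j)]);
          if (m > 0) Lnew += m * m;
        }
        Lnew *= C;
        const double obj_diff = Lnew - L0 + std::fabs(w[j] + zl) - std::fabs(w[j]);
        if (obj_diff <= sigma * lambda * delta_lin) break;
        lambda *= beta;
      }
      const double zl = lambda * z;
      w[j] += zl;
      for (int i = 0; i < n; ++i)
        fx[i] += zl * X[i + n * static_cast<R_xlen_t>(j)];
      if (std::fabs(zl) > max_step) max_step = std::fabs(zl);
    }
    if (max_step < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}
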