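#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic xorshift32 PRNG for coordinate-order permutations: the
// solver's sweeps are reproducible across runs and platforms and do not
// touch R's RNG stream.
static inline uint32_t xorshift32(uint32_t& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5;
  return s;
}

// L2-regularised, L1-loss (hinge) linear SVM trained in the dual by
// coordinate descent with randomly permuted sweeps (liblinear-style).
// The intercept, when requested by the caller, is an augmented constant
// feature supplied inside X and is therefore regularised; the solution w
// is unique, so predictions do not depend on the sweep order beyond the
// convergence tolerance.
//
// X row-major (n x d), y in {-1, +1}; alpha (length n) and w (length d)
// are used as warm starts and overwritten (they must be consistent:
// w = sum alpha_i y_i x_i).
static void dcd_train(const double* X, const int* y, int n, int d, double C,
                      const std::vector<double>& qii,
                      std::vector<double>& alpha, std::vector<double>& w,
                      double tol, int max_epoch, uint32_t rng_seed) {
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint32_t rs = rng_seed ? rng_seed : 1u;
  for (int epoch = 0; epoch < max_epoch; ++epoch) {
    // Fisher-Yates with the deterministic PRNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift32(rs) % (uint32_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      int i = order[t];
      if (qii[i] <= 0.0) continue;
      const double* xi = X + (size_t)i * d;
      double dec = 0.0;
      for (int j = 0; j < d; ++j) dec += w[j] * xi[j];
      double G = y[i] * dec - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      double apg = std::fabs(PG);
      if (apg > max_pg) max_pg = apg;
      if (apg > 1e-12) {
        double a_new = alpha[i] - G / qii[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        double delta = (a_new - alpha[i]) * y[i];
        alpha[i] = a_new;
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (max_pg < tol) break;
  }
}

// Leave-one-out accuracy for one feature matrix. Xfeat: n x p (column-major
// from R), y in {-1,+1}. Each fold is warm-started from the full-data
// solution with the held-out exemplar's contribution removed, then
// re-converged; the fold optimum is unique, so the warm start only saves
// sweeps. Ties (decision value exactly 0) predict +1.
static double loo_accuracy_raw(const NumericMatrix& Xfeat,
                               const IntegerVector& y,
                               double C, bool intercept,
                               double tol, int max_epoch) {
  const int n = Xfeat.nrow(), p = Xfeat.ncol();
  const int d = p + (intercept ? 1 : 0);
  std::vector<double> Xall((size_t)n * d);
  std::vector<int> yall(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) Xall[(size_t)i * d + j] = Xfeat(i, j);
    if (intercept) Xall[(size_t)i * d + p] = 1.0;
    yall[i] = y[i];
  }
  std::vector<double> qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double* xi = &Xall[(size_t)i * d];
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  // full-data solution as the warm-start base
  std::vector<double> alpha_full(n, 0.0), w_full(d, 0.0);
  dcd_train(Xall.data(), yall.data(), n, d, C, qii, alpha_full, w_full,
            tol, max_epoch, 2463534242u);

  std::vector<double> Xtr((size_t)(n - 1) * d), w(d), alpha(n - 1);
  std::vector<double> qtr(n - 1);
  std::vector<int> ytr(n - 1);
  int correct = 0;
  for (int hold = 0; hold < n; ++hold) {
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      std::copy(&Xall[(size_t)i * d], &Xall[(size_t)i * d] + d,
                &Xtr[(size_t)r * d]);
      ytr[r] = yall[i];
      qtr[r] = qii[i];
      alpha[r] = alpha_full[i];
      ++r;
    }
    for (int j = 0; j < d; ++j)
      w[j] = w_full[j] - alpha_full[hold] * yall[hold] * Xall[(size_t)hold * d + j];
    dcd_train(Xtr.data(), ytr.data(), n - 1, d, C, qtr, alpha, w,
              tol, max_epoch, 88675123u + (uint32_t)hold);
    double dec = 0.0;
    const double* xh = &Xall[(size_t)hold * d];
    for (int j = 0; j < d; ++j) dec += w[j] * xh[j];
    int pred = (dec >= 0.0) ? 1 : -1;
    if (pred == yall[hold]) ++correct;
  }
  return (double)correct / n;
}

// [[Rcpp::export]]
double cpp_loo_accuracy(NumericMatrix X, IntegerVector y, double C,
                        bool intercept, double tol, int max_epoch) {
  return loo_accuracy_raw(X, y, C, intercept, tol, max_epoch);
}

// Searchlight driver. B: n_exemplars x n_feature_voxels beta matrix;
// spheres: list of 1-based column-index vectors, one per valid centre.
// [[Rcpp::export]]
NumericVector cpp_searchlight_loo(NumericMatrix B, IntegerVector y,
                                  List spheres, double C, bool intercept,
                                  double tol, int max_epoch) {
  const int n = B.nrow();
  const int n_sph = spheres.size();
  NumericVector acc(n_sph);
  for (int s = 0; s < n_sph; ++s) {
    IntegerVector cols = spheres[s];
    const int p = cols.size();
    NumericMatrix Xs(n, p);
    for (int j = 0; j < p; ++j) {
      int cj = cols[j] - 1;
      for (int i = 0; i < n; ++i) Xs(i, j) = B(i, cj);
    }
    acc[s] = loo_accuracy_raw(Xs, y, C, intercept, tol, max_epoch);
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}

// Decision values of a single fit on all rows (used for margin checks and
// cross-validation against an external SVM in the tests).
// [[Rcpp::export]]
NumericVector cpp_svm_decision(NumericMatrix X, IntegerVector y, double C,
                               bool intercept, double tol, int max_epoch) {
  const int n = X.nrow(), p = X.ncol();
  const int d = p + (intercept ? 1 : 0);
  std::vector<double> Xall((size_t)n * d), w(d, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> yv(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) Xall[(size_t)i * d + j] = X(i, j);
    if (intercept) Xall[(size_t)i * d + p] = 1.0;
    yv[i] = y[i];
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += Xall[(size_t)i * d + j] * Xall[(size_t)i * d + j];
    qii[i] = s;
  }
  dcd_train(Xall.data(), yv.data(), n, d, C, qii, alpha, w,
            tol, max_epoch, 2463534242u);
  NumericVector dec(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += w[j] * Xall[(size_t)i * d + j];
    dec[i] = s;
  }
  return dec;
}
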