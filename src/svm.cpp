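#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

// Binary soft-margin SVM with RBF kernel, trained by sequential minimal
// optimization (the simplified variant with a random second index).
// Labels are +1 / -1. Small-n training only (kernel matrix is dense).

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_passes, int max_sweeps, int seed) {
  int n = X.nrow();
  std::vector<std::vector<double>> K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i][j] = K[j][i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> U(0, n - 1);

  auto f = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) s += alpha[j] * y[j] * K[i][j];
    return s;
  };

  int passes = 0, sweeps = 0;
  while (passes < max_passes && sweeps < max_sweeps) {
    ++sweeps;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = f(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = U(rng);
        while (j == i) j = U(rng);
        double Ej = f(j) - y[j];
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj - ai);
          H = std::min(C, C + aj - ai);
        } else {
          L = std::max(0.0, ai + aj - C);
          H = std::min(C, ai + aj);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[i][j] - K[i][i] - K[j][j];
        if (eta >= 0) continue;
        double ajn = aj - y[j] * (Ei - Ej) / eta;
        if (ajn > H) ajn = H;
        if (ajn < L) ajn = L;
        if (std::fabs(ajn - aj) < 1e-6) continue;
        double ain = ai + y[i] * y[j] * (aj - ajn);
        double b1 = b - Ei - y[i] * (ain - ai) * K[i][i]
          - y[j] * (ajn - aj) * K[i][j];
        double b2 = b - Ej - y[i] * (ain - ai) * K[i][j]
          - y[j] * (ajn - aj) * K[j][j];
        alpha[i] = ain; alpha[j] = ajn;
        if (ain > 0 && ain < C) b = b1;
        else if (ajn > 0 && ajn < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    if (changed == 0) ++passes; else passes = 0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["sweeps"] = sweeps);
}

// Decision values for new rows given support data.
// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  int n = Xtrain.nrow(), m = Xnew.nrow(), p = Xtrain.ncol();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] == 0.0) continue;
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = Xtrain(i, k) - Xnew(q, k);
        d2 += d * d;
      }
      s += alpha[i] * y[i] * std::exp(-gamma * d2);
    }
    out[q] = s;
  }
  return out;
}
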