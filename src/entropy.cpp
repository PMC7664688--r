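#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template match counts for approximate / sample entropy.
// Chebyshev (max-coordinate) distance between length-m templates.
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Sample entropy: B = matching template pairs (i < j) at length m,
// A = at length m + 1; SampEn = -log(A / B).
// Degenerate conventions: B == 0 -> 0; A == 0 -> -log(1 / Bpairs) cap.
// [[Rcpp::export]]
double sampen_cpp(NumericVector xx, int m, double r) {
  int n = xx.size();
  const double* x = xx.begin();
  if (n < m + 2) return 0.0;
  long long A = 0, B = 0;
  int nm = n - m; // templates of length m+1: i in [0, n-m-1]
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      if (cheb(x, i, j, m) <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0) return 0.0;
  if (A == 0) {
    long long tot = (long long)(nm) * (nm - 1) / 2;
    return std::log((double)tot);
  }
  return -std::log((double)A / (double)B);
}

// Approximate entropy: phi(m) - phi(m+1), self-matches included.
// [[Rcpp::export]]
double apen_cpp(NumericVector xx, int m, double r) {
  int n = xx.size();
  const double* x = xx.begin();
  if (n < m + 2) return 0.0;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nt = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j)
        if (cheb(x, i, j, mm) <= r) ++cnt;
      acc += std::log((double)cnt / (double)nt);
    }
    phi[s] = acc / nt;
  }
  return phi[0] - phi[1];
}

// Correlation sums for Grassberger-Procaccia: fraction of point pairs
// (separated by at least `theiler` samples in time) with Euclidean
// distance < r, for each radius. `emb` is n_points x dim.
// [[Rcpp::export]]
NumericVector corr_sum_cpp(NumericMatrix emb, NumericVector radii, int theiler) {
  int n = emb.nrow(), d = emb.ncol(), nr = radii.size();
  std::vector<long long> cnt(nr, 0);
  long long npairs = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double a = emb(i, k) - emb(j, k);
        s += a * a;
      }
      double dist = std::sqrt(s);
      ++npairs;
      for (int q = 0; q < nr; ++q)
        if (dist < radii[q]) ++cnt[q];
    }
  }
  NumericVector out(nr);
  for (int q = 0; q < nr; ++q)
    out[q] = npairs > 0 ? (double)cnt[q] / (double)npairs : 0.0;
  return out;
}
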