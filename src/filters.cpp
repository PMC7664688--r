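#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquads, direct form II transposed, single forward pass.
// sos rows: b0 b1 b2 a0 a1 a2, normalized so a0 == 1.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericVector x, NumericMatrix sos) {
  int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
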