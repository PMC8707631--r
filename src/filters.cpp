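#include <Rcpp.h>
using namespace Rcpp;

// Causal IIR filtering through a cascade of second-order sections.
// sos is a K x 6 matrix, one row per biquad: b0 b1 b2 a0 a1 a2 (a0 == 1).
// Direct form II transposed; zero initial state (signals start at rest).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  const int k = sos.nrow();
  const int n = x.size();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Centered moving average with window w (odd or even), edges truncated.
// Used for the MVC envelope; plain O(n) running sum.
// [[Rcpp::export(name = ".movavg_cpp")]]
NumericVector movavg_cpp(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1) stop("window must be >= 1");
  NumericVector y(n);
  const int half_lo = (w - 1) / 2, half_hi = w / 2;
  double acc = 0.0;
  int lo = 0, hi = -1; // current inclusive window [lo, hi]
  for (int i = 0; i < n; ++i) {
    const int want_lo = std::max(0, i - half_lo);
    const int want_hi = std::min(n - 1, i + half_hi);
    while (hi < want_hi) acc += x[++hi];
    while (lo < want_lo) acc -= x[lo++];
    y[i] = acc / (want_hi - want_lo + 1);
  }
  return y;
}
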