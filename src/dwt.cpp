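// Circular-convolution work-horses of the periodized DWT. The analysis
// step convolves with the filter and keeps odd (0-based) positions; the
// synthesis step is the adjoint (upsample back, circular correlation).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List dwt_step_cpp(NumericVector x, NumericVector lo, NumericVector hi) {
  int n = x.size(), L = lo.size(), m = n / 2;
  NumericVector a(m), d(m);
  for (int k = 0; k < m; ++k) {
    int t = 2 * k + 1;
    double sa = 0, sd = 0;
    for (int j = 0; j < L; ++j) {
      int idx = t - j;
      idx %= n;
      if (idx < 0) idx += n;
      double v = x[idx];
      sa += lo[j] * v;
      sd += hi[j] * v;
    }
    a[k] = sa; d[k] = sd;
  }
  return List::create(_["a"] = a, _["d"] = d);
}

// [[Rcpp::export]]
NumericVector idwt_step_cpp(NumericVector a, NumericVector d,
                            NumericVector lo, NumericVector hi) {
  int m = a.size(), n = 2 * m, L = lo.size();
  NumericVector x(n);
  for (int t = 0; t < n; ++t) {
    double s = 0;
    for (int j = 0; j < L; ++j) {
      int idx = (t + j) % n;
      if (idx % 2 == 1) {
        int k = (idx - 1) / 2;
        s += lo[j] * a[k] + hi[j] * d[k];
      }
    }
    x[t] = s;
  }
  return x;
}
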