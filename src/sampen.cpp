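#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy counts with Chebyshev distance, self-matches excluded.
// Returns (B, A): template matches of length m and m + 1.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  double B = 0.0, A = 0.0;
  for (int i = 0; i < n - m; ++i) {
    for (int j = i + 1; j < n - m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= r && d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
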