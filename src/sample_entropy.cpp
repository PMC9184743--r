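#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Sample entropy match counts: templates of length m are taken from the
// first N - m positions (Richman & Moorman / physionet convention, so the
// same template set is used for both lengths); pairs counted over i < j
// with Chebyshev distance <= r. Returns c(B, A) where B matches at length m
// and A additionally matches at position i+m vs j+m.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates
  if (nt < 2) stop("series too short for pattern length m");
  double B = 0.0, A = 0.0;
  const double *p = REAL(x);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(p[i + m] - p[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}
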