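#include <Rcpp.h>

// Template match counts for sample entropy, Chebyshev distance.
// Both template sets are indexed 1..N-m so the length-m and length-(m+1)
// counts are over the same pairs; self-matches excluded (i < j).
// Returns c(A, B): A = matches at length m+1, B = matches at length m.
// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts(const Rcpp::NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  const double* p = &x[0];
  double A = 0.0, B = 0.0;
  if (m == 1) {
    // dominant case: scalar templates, no inner loop
    for (int i = 0; i < nt - 1; ++i) {
      const double xi = p[i], xi1 = p[i + 1];
      for (int j = i + 1; j < nt; ++j) {
        if (std::fabs(xi - p[j]) <= r) {
          B += 1.0;
          if (std::fabs(xi1 - p[j + 1]) <= r) A += 1.0;
        }
      }
    }
  } else {
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        for (int w = 0; w < m; ++w) {
          const double dd = std::fabs(p[i + w] - p[j + w]);
          if (dd > d) d = dd;
        }
        if (d <= r) {
          B += 1.0;
          if (std::fabs(p[i + m] - p[j + m]) <= r) A += 1.0;
        }
      }
    }
  }
  return Rcpp::NumericVector::create(A, B);
}
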