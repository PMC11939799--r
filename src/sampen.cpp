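#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy.
// B = pairs (i < j), i,j in 0..n-m-1, with Chebyshev distance between the
//     length-m templates <= r (non-strict); A = same pairs at length m+1.
// Both counts range over the n-m templates for which an (m+1)-length
// extension exists, and self-matches are excluded by i < j.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of (m+1)-capable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dd = std::fabs(x[i + m] - x[j + m]);
      if (dd <= r && d <= r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
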