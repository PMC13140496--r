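#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy: Phi(m) - Phi(m+1) with Chebyshev distance,
// self-matches included, counts normalised per template.
// [[Rcpp::export(name = ".apen_core")]]
double apen_core(NumericVector x, int m, double r) {
  int n = x.size();
  double phi[2];
  for (int k = 0; k < 2; ++k) {
    int mm = m + k;
    int nt = n - mm + 1;
    if (nt < 1) return NA_REAL;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j) {
        double d = 0.0;
        for (int t = 0; t < mm; ++t) {
          double ad = std::fabs(x[i + t] - x[j + t]);
          if (ad > d) d = ad;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
      acc += std::log((double)cnt / nt);
    }
    phi[k] = acc / nt;
  }
  return phi[0] - phi[1];
}

// Sample entropy match counts: B over length-m templates, A over
// length-(m+1), ordered pairs i != j, both template indices restricted to
// 0..n-m-1 so that every pair counted for B also has an (m+1)-extension.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates 0..nt-1 have both m and m+1 versions
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int t = 0; t < m; ++t) {
        double ad = std::fabs(x[i + t] - x[j + t]);
        if (ad > d) d = ad;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r && d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
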