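#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman-Moorman).
// Templates of length m start at i = 0..N-m-1 so that every length-m
// template has a length-(m+1) extension; distance is Chebyshev.
// Returns c(A, B): A = matching pairs at length m+1, B = at length m.
// Self-matches excluded; each unordered pair counted once.
//
// Pairs are enumerated in order of the templates' first coordinate: once
// that coordinate alone differs by more than r the pair (and all later
// ones in the sweep) cannot match, so the scan stops early. The counts are
// exactly those of the naive double loop.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates
  double A = 0.0, B = 0.0;
  if (nt < 2) return NumericVector::create(0.0, 0.0);

  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  for (int a = 0; a < nt - 1; ++a) {
    const int i = ord[a];
    const double xi = x[i];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (x[j] - xi > r) break; // sorted first coordinate: no later match
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
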