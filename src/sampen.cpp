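#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Template match counts for sample entropy.
//
// Counts, over the n - m templates of length m (start indices 1..n-m), the
// unordered pairs whose Chebyshev distance is <= r (B), and of those, the
// pairs that still match when extended by one sample (A). Self-matches are
// excluded by construction. Templates are visited in order of their first
// coordinate so each template is only compared against the window of
// templates whose first coordinate lies within r; remaining coordinates are
// checked explicitly. This is O(n * k) with k the mean first-coordinate
// match count, with an O(n^2) worst case equal to the textbook double loop.
//
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int T = n - m; // number of templates that can be extended by one
  if (T < 2)
    stop("series too short for the requested template length");
  std::vector<int> idx(T);
  for (int i = 0; i < T; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });

  double A = 0.0, B = 0.0;
  if (m == 1) {
    // contiguous copies of (sorted first coordinate, its successor) so the
    // inner window scan is cache-friendly
    std::vector<double> xs(T), xn(T);
    for (int p = 0; p < T; ++p) { xs[p] = x[idx[p]]; xn[p] = x[idx[p] + 1]; }
    for (int p = 0; p < T; ++p) {
      const double lim = xs[p] + r;
      for (int q = p + 1; q < T && xs[q] <= lim; ++q) {
        B += 1.0;
        if (std::fabs(xn[q] - xn[p]) <= r) A += 1.0;
      }
    }
    return List::create(_["A"] = A, _["B"] = B);
  }
  for (int p = 0; p < T; ++p) {
    const int i = idx[p];
    for (int q = p + 1; q < T; ++q) {
      const int j = idx[q];
      if (x[j] - x[i] > r) break; // sorted: no further first-coord matches
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
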