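#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Pooled sample-entropy template counts over discontinuous segments.
//
// Templates of length m (extendable to m+1) are enumerated within each
// segment only — no template spans a segment boundary — but template PAIRS
// are compared across the whole pool, so counts from all segments enter a
// single log-ratio. Following Richman & Moorman, only the first L - m
// template positions of a length-L segment are used, so every m-template
// has an (m+1)-th point and A <= B holds by construction.
//
// A pair matches at length k when the Chebyshev distance over the first k
// points is <= tol (non-strict, so ties count as matches). Self-matches are
// excluded. Templates are sorted by first coordinate so only pairs whose
// first coordinates already lie within tol are examined.
//
// [[Rcpp::export(name = ".sampen_counts")]]
List sampen_counts(List segments, int m, double tol) {
  if (m < 1) stop("m must be >= 1");
  if (tol < 0) stop("tolerance must be non-negative");

  std::vector<double> x;
  std::vector<int> starts;  // index into x of each template's first point
  for (R_xlen_t s = 0; s < segments.size(); ++s) {
    NumericVector seg(segments[s]);
    int L = seg.size();
    int off = x.size();
    for (int i = 0; i < L; ++i) x.push_back(seg[i]);
    for (int i = 0; i + m < L; ++i) starts.push_back(off + i);
  }
  int nt = starts.size();
  double A = 0.0, B = 0.0;
  if (nt < 2) return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);

  std::sort(starts.begin(), starts.end(),
            [&x](int a, int b) { return x[a] < x[b]; });

  // pack templates contiguously in sorted order for cache-friendly scans
  const int w = m + 1;
  std::vector<double> tp((size_t)nt * w);
  for (int i = 0; i < nt; ++i)
    for (int t = 0; t < w; ++t) tp[(size_t)i * w + t] = x[starts[i] + t];

  const double* xd = tp.data();
  for (int i = 0; i < nt - 1; ++i) {
    const double* ti = xd + (size_t)i * w;
    const double lim = ti[0] + tol;
    for (int j = i + 1; j < nt; ++j) {
      const double* tj = xd + (size_t)j * w;
      if (tj[0] > lim) break;  // sorted: no further first-coordinate matches
      bool ok = true;
      for (int t = 1; t < m; ++t) {
        double d = ti[t] - tj[t];
        if (d > tol || d < -tol) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = ti[m] - tj[m];
      if (d <= tol && d >= -tol) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);
}
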