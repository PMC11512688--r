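#include <Rcpp.h>
using namespace Rcpp;

// Zero-delay FIR filtering of each row of a channels x samples matrix with a
// symmetric odd-length kernel. Edges use reflection padding, matching the
// R-side convention.
// [[Rcpp::export(name = ".fir_rows_cpp")]]
NumericMatrix fir_rows(NumericMatrix x, NumericVector h) {
  const int L = h.size();
  if (L % 2 == 0) stop("kernel length must be odd");
  const int d = (L - 1) / 2;
  const int nc = x.nrow(), n = x.ncol();
  if (d >= n) stop("signal shorter than filter delay");
  NumericMatrix out(nc, n);
  std::vector<double> row(n), hh(h.begin(), h.end());
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < n; ++i) row[i] = x(c, i);
    // edges, with index reflection
    for (int i = 0; i < std::min(d, n); ++i) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k) {
        int j = i + k - d;
        if (j < 0) j = -j; else if (j >= n) j = 2 * n - 2 - j;
        acc += hh[k] * row[j];
      }
      out(c, i) = acc;
    }
    for (int i = std::max(d, n - d); i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < L; ++k) {
        int j = i + k - d;
        if (j < 0) j = -j; else if (j >= n) j = 2 * n - 2 - j;
        acc += hh[k] * row[j];
      }
      out(c, i) = acc;
    }
    // interior, branch-free
    for (int i = d; i < n - d; ++i) {
      double acc = 0.0;
      const double* xp = row.data() + i - d;
      for (int k = 0; k < L; ++k) acc += hh[k] * xp[k];
      out(c, i) = acc;
    }
  }
  return out;
}
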