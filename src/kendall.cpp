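#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Knight's O(n log n) Kendall tau-a via merge-sort inversion counting.
// Assumes effectively continuous data (no ties); ties are handled by the
// R-level wrapper, which falls back to stats::cor for small tied samples.

static long long merge_count(std::vector<double> &y, std::vector<double> &buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {
      buf[k++] = y[j++];
      inv += (long long)(mid - i);
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

// [[Rcpp::export(name = ".kendall_tau_a")]]
double kendall_tau_a(Rcpp::NumericVector x, Rcpp::NumericVector y) {
  size_t n = x.size();
  if (y.size() != (R_xlen_t)n) Rcpp::stop("x and y must have equal length");
  if (n < 2) Rcpp::stop("need at least two observations");
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n), buf(n);
  for (size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];
  long long inv = merge_count(ys, buf, 0, n);
  double n0 = (double)n * (n - 1.0) / 2.0;
  return (n0 - 2.0 * (double)inv) / n0;
}
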