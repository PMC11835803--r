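#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Ordered template-pair counts for sample entropy.
//
// Templates of length m and m+1 are both taken over start indices
// i = 0..n-m-1 (1-based 1..N-m) so the pair sets nest and the
// conditional ratio is guaranteed <= 1. Self-pairs (i == j) are
// excluded; (i, j) and (j, i) both count, hence the factor 2.
// A pair matches when the Chebyshev distance is <= r.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // shared template range for both lengths
  const double *xp = REAL(x);
  double count_m = 0.0, count_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *xi = xp + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *xj = xp + j;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        const double d = xi[k] - xj[k];
        if (d > r || d < -r) { ok = false; break; }
      }
      if (ok) {
        count_m += 2.0;
        const double d = xi[m] - xj[m];
        if (d <= r && d >= -r) count_m1 += 2.0;
      }
    }
  }
  return NumericVector::create(count_m, count_m1);
}

// Sliding-window range (max - min) over windows of w samples advancing
// one sample at a time; returns n - w + 1 values. Monotonic-deque
// implementation, O(n).
// [[Rcpp::export]]
NumericVector rolling_range_cpp(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1 || w > n) stop("window must be in 1..length(x)");
  const int nout = n - w + 1;
  NumericVector out(nout);
  std::deque<int> qmax, qmin;
  for (int i = 0; i < n; ++i) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    const int lo = i - w + 1;
    if (lo >= 0) {
      while (qmax.front() < lo) qmax.pop_front();
      while (qmin.front() < lo) qmin.pop_front();
      out[lo] = x[qmax.front()] - x[qmin.front()];
    }
  }
  return out;
}
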