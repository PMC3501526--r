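#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding-window extreme with per-point half-widths (monotone deque).
// Output i is min/max of x over [i - half[i], i + half[i]] clipped to the
// vector. Half-widths proportional to an ascending m/z grid give window
// endpoints that are non-decreasing in i; endpoints are clamped to enforce
// monotonicity so the deque invariant always holds.
// [[Rcpp::export(name = ".roll_extreme")]]
NumericVector roll_extreme(NumericVector x, IntegerVector half, bool do_min) {
  int n = x.size();
  if (half.size() != n) stop("length mismatch between x and half");
  NumericVector out(n);
  std::deque<int> dq;
  int r = -1, l = 0;
  for (int i = 0; i < n; ++i) {
    int ri = i + half[i];
    if (ri > n - 1) ri = n - 1;
    if (ri < r) ri = r;
    int li = i - half[i];
    if (li < 0) li = 0;
    if (li < l) li = l;
    for (int j = r + 1; j <= ri; ++j) {
      if (do_min) {
        while (!dq.empty() && x[dq.back()] >= x[j]) dq.pop_back();
      } else {
        while (!dq.empty() && x[dq.back()] <= x[j]) dq.pop_back();
      }
      dq.push_back(j);
    }
    r = ri;
    while (!dq.empty() && dq.front() < li) dq.pop_front();
    l = li;
    out[i] = x[dq.front()];
  }
  return out;
}
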