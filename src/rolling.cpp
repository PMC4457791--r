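#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered rolling extrema with a monotonic deque, O(n). The window shrinks
// at the boundaries (min/max over the in-range part only), which keeps the
// morphological opening built on top of these idempotent.
static NumericVector roll_extreme(const NumericVector& x, int k, bool minimum) {
  int n = x.size();
  if (k < 1) stop("window must be >= 1");
  if (k % 2 == 0) stop("window must be odd");
  int h = k / 2;
  NumericVector out(n);
  std::deque<int> q;  // indices, values monotone
  int right = -1;
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n - 1, i + h);
    int lo = std::max(0, i - h);
    while (right < hi) {
      ++right;
      double v = x[right];
      if (minimum) {
        while (!q.empty() && x[q.back()] >= v) q.pop_back();
      } else {
        while (!q.empty() && x[q.back()] <= v) q.pop_back();
      }
      q.push_back(right);
    }
    while (!q.empty() && q.front() < lo) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}

// [[Rcpp::export(name = ".rollMin")]]
NumericVector roll_min(NumericVector x, int k) { return roll_extreme(x, k, true); }

// [[Rcpp::export(name = ".rollMax")]]
NumericVector roll_max(NumericVector x, int k) { return roll_extreme(x, k, false); }
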