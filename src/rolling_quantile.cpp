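#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered rolling quantile with edge truncation.
//
// For frame i (0-based) the window is [i - half, i + half] intersected with
// [0, n), half = floor(window / 2).  Quantile is type-7 (linear interpolation
// between order statistics), matching stats::quantile defaults so R-side
// oracles can reproduce every value exactly.
//
// The window is maintained as a sorted vector with binary-search
// insert/erase per step, so the cost per frame is one memmove of at most
// `window` doubles instead of a full partial sort.
// [[Rcpp::export(name = ".rolling_quantile_cpp")]]
NumericVector rolling_quantile_cpp(NumericVector x, int window, double prob) {
  const int n = x.size();
  if (window < 1) stop("window must be >= 1");
  if (prob < 0.0 || prob > 1.0) stop("prob must be in [0, 1]");
  const int half = window / 2;
  NumericVector out(n);

  std::vector<double> buf;                     // sorted current window
  buf.reserve(2 * (size_t)half + 2);
  const int hi0 = std::min(n - 1, half);
  for (int j = 0; j <= hi0; ++j) buf.push_back(x[j]);
  std::sort(buf.begin(), buf.end());

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const int add = i + half;                // new right edge
      if (add <= n - 1) {
        buf.insert(std::upper_bound(buf.begin(), buf.end(), x[add]), x[add]);
      }
      const int drop = i - 1 - half;           // old left edge leaves
      if (drop >= 0) {
        buf.erase(std::lower_bound(buf.begin(), buf.end(), x[drop]));
      }
    }
    const int m = (int)buf.size();
    const double h = (m - 1) * prob;
    const int k = (int)std::floor(h);
    const double xk = buf[k];
    out[i] = (k + 1 < m && h > k) ? xk + (h - k) * (buf[k + 1] - xk) : xk;
  }
  return out;
}
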