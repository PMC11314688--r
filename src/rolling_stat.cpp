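#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Rolling k-th smallest over all contiguous windows of length n (stride 1).
// Two-multiset technique: `low` holds the k smallest of the window, `high`
// the rest; the k-th smallest is the maximum of `low`. O(N log n).
// [[Rcpp::export(name = ".roll_kth_smallest")]]
NumericVector roll_kth_smallest(NumericVector x, int n, int k) {
  int N = x.size();
  if (n <= 0 || n > N) stop("window length out of range");
  if (k < 1 || k > n) stop("order statistic out of range");
  int nw = N - n + 1;
  NumericVector out(nw);
  std::multiset<double> low, high;

  auto rebalance = [&]() {
    while ((int)low.size() > k) {
      auto it = std::prev(low.end());
      high.insert(*it);
      low.erase(it);
    }
    while ((int)low.size() < k && !high.empty()) {
      auto it = high.begin();
      low.insert(*it);
      high.erase(it);
    }
  };
  auto insert_val = [&](double v) {
    if (low.empty() || v <= *low.rbegin()) low.insert(v);
    else high.insert(v);
    rebalance();
  };
  auto erase_val = [&](double v) {
    auto it = low.find(v);
    if (it != low.end()) low.erase(it);
    else high.erase(high.find(v));
    rebalance();
  };

  for (int i = 0; i < n; ++i) insert_val(x[i]);
  out[0] = *low.rbegin();
  for (int i = 1; i < nw; ++i) {
    erase_val(x[i - 1]);
    insert_val(x[i + n - 1]);
    out[i] = *low.rbegin();
  }
  return out;
}

// Rolling mean over all contiguous windows of length n (stride 1), with
// compensated summation to keep exactness on long days.
// [[Rcpp::export(name = ".roll_mean")]]
NumericVector roll_mean(NumericVector x, int n) {
  int N = x.size();
  if (n <= 0 || n > N) stop("window length out of range");
  int nw = N - n + 1;
  NumericVector out(nw);
  long double s = 0.0;
  for (int i = 0; i < n; ++i) s += x[i];
  out[0] = (double)(s / n);
  for (int i = 1; i < nw; ++i) {
    s += x[i + n - 1] - x[i - 1];
    out[i] = (double)(s / n);
  }
  return out;
}
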