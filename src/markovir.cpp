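#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Rolling (k+1)-mer index over base codes (A=0,C=1,G=2,T=3; NA = ambiguous).
// Returns 1-based indices into the lexicographic table of 4^(k+1) words;
// any window touching an ambiguous base is NA. O(n) with a last-bad tracker.
// [[Rcpp::export]]
IntegerVector cpp_window_index(IntegerVector codes, int k) {
  int n = codes.size();
  int m = n - k;
  if (m < 1) return IntegerVector(0);
  IntegerVector out(m);
  long long base = 1;
  for (int j = 0; j <= k; ++j) base *= 4;
  long long idx = 0;
  int last_bad = -n - 1;
  for (int i = 0; i < n; ++i) {
    int c = codes[i];
    if (c == NA_INTEGER) {
      last_bad = i;
      idx = (idx * 4) % base;
    } else {
      idx = (idx * 4 + c) % base;
    }
    int start = i - k;
    if (start >= 0)
      out[start] = (last_bad >= start) ? NA_INTEGER : (int)(idx + 1);
  }
  return out;
}

// Simulate n bases from a k-th order Markov chain. `cum` is the 4^k x 4
// row-cumulative transition matrix (last column 1); `init_cum` the cumulative
// initial distribution over the 4^k starting contexts. Uses R's RNG so
// set.seed() makes draws reproducible. Returns base codes 0..3.
// [[Rcpp::export]]
IntegerVector cpp_simulate_markov(int n, int k, NumericMatrix cum,
                                  NumericVector init_cum) {
  if (n < k + 1) stop("sequence length must be at least order + 1");
  int nctx = cum.nrow();
  IntegerVector out(n);
  int ctx = 0;
  if (k > 0) {
    double u = unif_rand();
    ctx = std::lower_bound(init_cum.begin(), init_cum.end(), u) -
          init_cum.begin();
    if (ctx >= nctx) ctx = nctx - 1;
    int tmp = ctx;
    for (int j = k - 1; j >= 0; --j) {
      out[j] = tmp % 4;
      tmp /= 4;
    }
  }
  for (int i = k; i < n; ++i) {
    double u = unif_rand();
    int c = 0;
    while (c < 3 && cum(ctx, c) < u) ++c;
    out[i] = c;
    ctx = (int)(((long long)ctx * 4 + c) % nctx);
  }
  return out;
}
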