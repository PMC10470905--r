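#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact univariate k-means by dynamic programming over sorted values.
// xs must be sorted ascending. For every k in 1..kmax returns the minimal
// within-cluster sum of squares and the cluster boundaries (1-based start
// index of each cluster in the sorted order). Cost of a contiguous block is
// evaluated with prefix sums of values centered at the overall mean for
// numerical stability.
// [[Rcpp::export]]
List ckmeans_dp(NumericVector xs, int kmax) {
  const int n = xs.size();
  if (n < 1) stop("empty input");
  if (kmax < 1) stop("kmax must be >= 1");
  if (kmax > n) kmax = n;

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += xs[i];
  mu /= n;

  std::vector<long double> s1(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    long double v = (long double)xs[i] - mu;
    s1[i + 1] = s1[i] + v;
    s2[i + 1] = s2[i] + v * v;
  }
  // within-SS of block [j..i] (1-based inclusive)
  auto cost = [&](int j, int i) -> long double {
    long double sum = s1[i] - s1[j - 1];
    long double sq = s2[i] - s2[j - 1];
    int len = i - j + 1;
    long double c = sq - sum * sum / len;
    return c > 0 ? c : 0.0L;
  };

  // D[k][i]: optimal cost of first i points in k clusters; B: backpointers
  std::vector<std::vector<long double>> D(kmax + 1,
      std::vector<long double>(n + 1, 0.0L));
  std::vector<std::vector<int>> B(kmax + 1, std::vector<int>(n + 1, 1));
  for (int i = 1; i <= n; ++i) {
    D[1][i] = cost(1, i);
    B[1][i] = 1;
  }
  for (int k = 2; k <= kmax; ++k) {
    for (int i = k; i <= n; ++i) {
      long double best = -1.0L;
      int arg = k;
      for (int j = k; j <= i; ++j) {   // cluster k is [j..i]
        long double c = D[k - 1][j - 1] + cost(j, i);
        if (best < 0 || c < best) { best = c; arg = j; }
      }
      D[k][i] = best;
      B[k][i] = arg;
    }
  }

  NumericVector within(kmax);
  List breaks(kmax);
  for (int k = 1; k <= kmax; ++k) {
    if (k > n) continue;
    within[k - 1] = (double)D[k][n];
    IntegerVector starts(k);
    int i = n;
    for (int kk = k; kk >= 1; --kk) {
      starts[kk - 1] = B[kk][i];
      i = B[kk][i] - 1;
    }
    breaks[k - 1] = starts;
  }
  return List::create(_["within_ss"] = within, _["starts"] = breaks);
}
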