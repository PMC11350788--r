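#include <Rcpp.h>
using namespace Rcpp;

// Fisher's optimal 1-D partition (natural breaks): dynamic program over
// sorted values minimizing the total within-class sum of squared deviations.
// Returns the 1-based start index of each class in the sorted vector.
// [[Rcpp::export]]
IntegerVector jenks_dp(NumericVector x, int k) {
  const int n = x.size();
  if (k < 2 || k > n) stop("need 2 <= k <= n");
  // center on the global mean and accumulate in long double: the
  // sum-of-squares identity cancels catastrophically otherwise
  long double mean = 0.0L;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  std::vector<long double> s(n + 1, 0.0L), s2(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    const long double c = x[i] - mean;
    s[i + 1] = s[i] + c;
    s2[i + 1] = s2[i] + c * c;
  }
  // ssd of x[i..j], 0-based inclusive
  auto cost = [&](int i, int j) -> double {
    const long double sum = s[j + 1] - s[i];
    const int cnt = j - i + 1;
    return (double)(s2[j + 1] - s2[i] - sum * sum / cnt);
  };
  const double INF = std::numeric_limits<double>::infinity();
  // D[m][j]: best cost of splitting x[0..j] into m+1 classes
  std::vector<std::vector<double>> D(k, std::vector<double>(n, INF));
  std::vector<std::vector<int>> back(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) D[0][j] = cost(0, j);
  for (int m = 1; m < k; ++m) {
    for (int j = m; j < n; ++j) {
      double best = INF; int arg = m;
      for (int i = m; i <= j; ++i) {          // class m starts at i
        const double c = D[m - 1][i - 1] + cost(i, j);
        if (c < best) { best = c; arg = i; }
      }
      D[m][j] = best;
      back[m][j] = arg;
    }
  }
  IntegerVector starts(k);
  int j = n - 1;
  for (int m = k - 1; m >= 1; --m) {
    starts[m] = back[m][j] + 1;  // 1-based
    j = back[m][j] - 1;
  }
  starts[0] = 1;
  starts.attr("ssd") = D[k - 1][n - 1];
  return starts;
}
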