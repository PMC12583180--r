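#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher-Jenks optimal 1-D classification.
//
// Dynamic programme over the sorted sample minimising the total within-class
// sum of squared deviations. O(k n^2) time with O(k n) backtracking storage;
// class costs come from prefix sums, so the optimum is exact (no k-means-style
// initialisation dependence).
//
// Returns the n_classes - 1 interior break values (upper edge of each class
// but the last, taken as data values) with the optimal objective attached.
// [[Rcpp::export(name = ".jenks_cpp")]]
NumericVector jenks_cpp(NumericVector values, int n_classes) {
  NumericVector x = clone(values).sort();
  int n = x.size();
  if (n_classes < 1) stop("n_classes must be >= 1");
  if (n < n_classes) stop("need at least n_classes values");

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  // ssq of x[i..j], 0-based inclusive
  auto ssq = [&](int i, int j) {
    double s = cs[j + 1] - cs[i];
    int m = j - i + 1;
    return cs2[j + 1] - cs2[i] - s * s / m;
  };

  const double INF = R_PosInf;
  std::vector<double> prev(n, 0.0), cur(n, 0.0);
  // backtrack[k][j] = start index of class k+1 ending at j
  std::vector<std::vector<int>> back(n_classes, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) { prev[j] = ssq(0, j); back[0][j] = 0; }
  for (int k = 1; k < n_classes; ++k) {
    for (int j = n - 1; j >= k; --j) {
      double best = INF; int bi = k;
      for (int i = k; i <= j; ++i) {
        double c = prev[i - 1] + ssq(i, j);
        if (c < best) { best = c; bi = i; }
      }
      cur[j] = best; back[k][j] = bi;
    }
    std::swap(prev, cur);
  }

  // recover class boundaries
  std::vector<int> starts(n_classes);
  int j = n - 1;
  for (int k = n_classes - 1; k >= 0; --k) {
    starts[k] = back[k][j];
    j = starts[k] - 1;
  }
  NumericVector breaks(n_classes - 1);
  for (int k = 1; k < n_classes; ++k) breaks[k - 1] = x[starts[k] - 1];
  breaks.attr("objective") = prev[n - 1];
  return breaks;
}
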