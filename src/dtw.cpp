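// Banded dynamic time warping (Sakoe-Chiba) by dynamic programming.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
double dtw_cost(NumericVector a, NumericVector b, int window, bool squared) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty trace");
  const double INF = std::numeric_limits<double>::infinity();
  // band must at least cover the length difference for a path to exist
  const int w = std::max(window, std::abs(n - m));
  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    const int j0 = std::max(1, i - w), j1 = std::min(m, i + w);
    for (int j = j0; j <= j1; ++j) {
      const double d = a[i - 1] - b[j - 1];
      const double c = squared ? d * d : std::fabs(d);
      const double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise DTW distances between rows of A and rows of B.
// [[Rcpp::export]]
NumericMatrix dtw_cross(NumericMatrix A, NumericMatrix B, int window,
                        bool squared) {
  const int na = A.nrow(), nb = B.nrow();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i) {
    NumericVector ai = A(i, _);
    for (int j = 0; j < nb; ++j) {
      D(i, j) = dtw_cost(ai, B(j, _), window, squared);
    }
  }
  return D;
}
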