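#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static inline double local_cost(double a, double b, bool squared) {
  double d = a - b;
  return squared ? d * d : std::fabs(d);
}

// Exact DTW cost, standard boundary initialization (first row/column
// accumulate), O(M) memory.
// [[Rcpp::export]]
double cpp_dtw(NumericVector x, NumericVector y, bool squared) {
  int N = x.size(), M = y.size();
  std::vector<double> prev(M), cur(M);
  prev[0] = local_cost(x[0], y[0], squared);
  for (int j = 1; j < M; ++j) prev[j] = prev[j - 1] + local_cost(x[0], y[j], squared);
  for (int i = 1; i < N; ++i) {
    cur[0] = prev[0] + local_cost(x[i], y[0], squared);
    for (int j = 1; j < M; ++j) {
      double best = std::min(cur[j - 1], std::min(prev[j], prev[j - 1]));
      cur[j] = best + local_cost(x[i], y[j], squared);
    }
    std::swap(prev, cur);
  }
  return prev[M - 1];
}

// DTW restricted to a band: row i may only use columns lo[i]..hi[i]
// (1-based inclusive, from R). Returns the cost and the optimal warping path.
// [[Rcpp::export]]
List cpp_dtw_band(NumericVector x, NumericVector y,
                  IntegerVector lo, IntegerVector hi, bool squared) {
  int N = x.size(), M = y.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix D(N, M);
  std::fill(D.begin(), D.end(), INF);
  for (int i = 0; i < N; ++i) {
    int jlo = lo[i] - 1, jhi = hi[i] - 1;
    for (int j = jlo; j <= jhi; ++j) {
      double c = local_cost(x[i], y[j], squared);
      if (i == 0 && j == 0) { D(i, j) = c; continue; }
      double best = INF;
      if (j > jlo)        best = std::min(best, D(i, j - 1));
      if (i > 0 && j >= lo[i-1]-1 && j <= hi[i-1]-1)     best = std::min(best, D(i - 1, j));
      if (i > 0 && j-1 >= lo[i-1]-1 && j-1 <= hi[i-1]-1) best = std::min(best, D(i - 1, j - 1));
      if (best == INF) continue; // unreachable cell
      D(i, j) = best + c;
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = N - 1, j = M - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double dd = INF, dl = INF, du = INF;
    if (i > 0 && j > 0) dd = D(i - 1, j - 1);
    if (j > 0)          dl = D(i, j - 1);
    if (i > 0)          du = D(i - 1, j);
    if (dd <= dl && dd <= du)      { --i; --j; }
    else if (du <= dl)             { --i; }
    else                           { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = D(N - 1, M - 1),
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}
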