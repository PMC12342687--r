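#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline double pcost(double a, double b, bool squared) {
  double d = a - b;
  return squared ? d * d : std::fabs(d);
}

// Cumulative DTW cost by row sweep.  The recurrence is
//   D[i,j] = cost(x_i, y_j) + min(D[i-1,j], D[i,j-1], D[i-1,j-1])
// anchored at D[1,1] = cost(x_1, y_1).  `band` < 0 disables the
// Sakoe-Chiba constraint; otherwise the effective radius is widened to
// |n - m| so the corner cell stays reachable.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y, bool squared, int band) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty sequence");
  int r = band;
  if (r >= 0 && r < std::abs(n - m)) r = std::abs(n - m);
  const double INF = R_PosInf;
  std::vector<double> prev(m, INF), cur(m, INF);
  for (int i = 0; i < n; ++i) {
    int j0 = 0, j1 = m - 1;
    if (r >= 0) {
      j0 = std::max(0, i - r);
      j1 = std::min(m - 1, i + r);
    }
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = j0; j <= j1; ++j) {
      double c = pcost(x[i], y[j], squared);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        double up   = (i > 0) ? prev[j]     : INF;
        double left = (j > 0) ? cur[j - 1]  : INF;
        double diag = (i > 0 && j > 0) ? prev[j - 1] : INF;
        best = std::min(diag, std::min(up, left));
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Distances for an explicit list of index pairs (1-based into `signals`).
// Each pair is independent, so results do not depend on evaluation order.
// [[Rcpp::export]]
NumericVector dtw_pairs_cpp(List signals, IntegerVector ii, IntegerVector jj,
                            bool squared, int band) {
  const int np = ii.size();
  if (jj.size() != np) stop("index vectors differ in length");
  const int ns = signals.size();
  std::vector<NumericVector> sig(ns);
  for (int k = 0; k < ns; ++k) sig[k] = as<NumericVector>(signals[k]);
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    int a = ii[p], b = jj[p];
    if (a < 1 || a > ns || b < 1 || b > ns) stop("pair index out of range");
    out[p] = dtw_cost_cpp(sig[a - 1], sig[b - 1], squared, band);
  }
  return out;
}
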