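#include <Rcpp.h>
using namespace Rcpp;

static inline double local_d(double x, double y, int metric) {
  double d = x - y;
  if (metric == 0) return std::abs(d);   // absolute difference
  return d * d;                          // squared difference
}

// Fill the DTW accumulated-cost matrix. window < 0 means unconstrained;
// otherwise a Sakoe-Chiba band |k - j| <= window (on scaled indices for
// unequal lengths).
static NumericMatrix dtw_cost(const NumericVector& x, const NumericVector& y,
                              int metric, int window) {
  int M = x.size(), N = y.size();
  NumericMatrix C(M, N);
  double inf = R_PosInf;
  std::fill(C.begin(), C.end(), inf);
  double ratio = (double)N / (double)M;
  for (int k = 0; k < M; ++k) {
    int jlo = 0, jhi = N - 1;
    if (window >= 0) {
      int centre = (int)std::round(k * ratio);
      jlo = std::max(0, centre - window);
      jhi = std::min(N - 1, centre + window);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = local_d(x[k], y[j], metric);
      if (k == 0 && j == 0) {
        C(0, 0) = d;
      } else {
        double best = inf;
        if (k > 0 && C(k - 1, j) < best) best = C(k - 1, j);
        if (k > 0 && j > 0 && C(k - 1, j - 1) < best) best = C(k - 1, j - 1);
        if (j > 0 && C(k, j - 1) < best) best = C(k, j - 1);
        C(k, j) = d + best;
      }
    }
  }
  return C;
}

// [[Rcpp::export(name = ".dtw_dp")]]
List dtw_dp(NumericVector x, NumericVector y, int metric, int window) {
  int M = x.size(), N = y.size();
  NumericMatrix C = dtw_cost(x, y, metric, window);
  // backtrack the optimal warping path from (M, N) to (1, 1)
  std::vector<int> pk, pj;
  int k = M - 1, j = N - 1;
  pk.push_back(k + 1); pj.push_back(j + 1);
  while (k > 0 || j > 0) {
    if (k == 0) { --j; }
    else if (j == 0) { --k; }
    else {
      double a = C(k - 1, j - 1), b = C(k - 1, j), c = C(k, j - 1);
      if (a <= b && a <= c) { --k; --j; }
      else if (b <= c) { --k; }
      else { --j; }
    }
    pk.push_back(k + 1); pj.push_back(j + 1);
  }
  std::reverse(pk.begin(), pk.end());
  std::reverse(pj.begin(), pj.end());
  double dist = C(M - 1, N - 1);
  if (metric == 2) dist = std::sqrt(dist);  // euclidean: sqrt of summed squares
  return List::create(_["distance"] = dist,
                      _["path"] = cbind(IntegerVector(pk.begin(), pk.end()),
                                        IntegerVector(pj.begin(), pj.end())));
}

// [[Rcpp::export(name = ".dtw_all_pairs")]]
NumericMatrix dtw_all_pairs(NumericMatrix series, int metric, int window) {
  int N = series.nrow();
  NumericMatrix D(N, N);
  for (int i = 0; i < N - 1; ++i) {
    NumericVector xi = series(i, _);
    for (int j = i + 1; j < N; ++j) {
      NumericVector xj = series(j, _);
      NumericMatrix C = dtw_cost(xi, xj, metric, window);
      double dist = C(xi.size() - 1, xj.size() - 1);
      if (metric == 2) dist = std::sqrt(dist);
      D(i, j) = dist;
      D(j, i) = dist;
    }
  }
  return D;
}
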