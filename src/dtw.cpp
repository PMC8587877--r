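#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

inline double sqdiff(double x, double y) {
  const double d = x - y;
  return d * d;
}

// Accumulated cost matrix with a sentinel row/column:
// D(0,0) = 0, D(0, 1..n) = D(1..m, 0) = +Inf,
// D(i,j) = (a_i - b_j)^2 + min(D(i-1,j), D(i,j-1), D(i-1,j-1)).
// Stored row-major as an (m+1) x (n+1) flat vector.
std::vector<double> acc_cost(const NumericVector& a, const NumericVector& b) {
  const int m = a.size(), n = b.size();
  const int w = n + 1;
  std::vector<double> D((m + 1) * w, R_PosInf);
  D[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double best = D[(i - 1) * w + (j - 1)];
      const double up = D[(i - 1) * w + j];
      const double left = D[i * w + (j - 1)];
      if (up < best) best = up;
      if (left < best) best = left;
      D[i * w + j] = sqdiff(a[i - 1], b[j - 1]) + best;
    }
  }
  return D;
}

// Backtrack the optimal warping path from (m, n) to (1, 1).  Ties between
// predecessors are broken deterministically: diagonal (i-1, j-1) first,
// then (i-1, j), then (i, j-1).  Pairs are returned in forward order.
void backtrack(const std::vector<double>& D, int m, int n,
               std::vector<int>& pi, std::vector<int>& pj) {
  const int w = n + 1;
  int i = m, j = n;
  pi.push_back(i);
  pj.push_back(j);
  while (i > 1 || j > 1) {
    const double diag = D[(i - 1) * w + (j - 1)];
    const double up = D[(i - 1) * w + j];
    const double left = D[i * w + (j - 1)];
    double best = diag;
    if (up < best) best = up;
    if (left < best) best = left;
    if (diag == best) {
      --i; --j;
    } else if (up == best) {
      --i;
    } else {
      --j;
    }
    pi.push_back(i);
    pj.push_back(j);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
}

}  // namespace

// [[Rcpp::export]]
double cpp_dtw_distance(NumericVector a, NumericVector b) {
  const std::vector<double> D = acc_cost(a, b);
  return D[a.size() * (b.size() + 1) + b.size()];
}

// [[Rcpp::export]]
List cpp_dtw_path(NumericVector a, NumericVector b) {
  const int m = a.size(), n = b.size();
  const std::vector<double> D = acc_cost(a, b);
  std::vector<int> pi, pj;
  backtrack(D, m, n, pi, pj);
  const int L = static_cast<int>(pi.size());
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[k];
    path(k, 1) = pj[k];
  }
  return List::create(_["path"] = path, _["distance"] = D[m * (n + 1) + n]);
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_pairwise(List series) {
  const int n = series.size();
  NumericMatrix M(n, n);
  std::vector<NumericVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = cpp_dtw_distance(s[i], s[j]);
      M(i, j) = d;
      M(j, i) = d;
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_dtw_to_many(NumericVector center, List series) {
  const int n = series.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cpp_dtw_distance(center, as<NumericVector>(series[i]));
  return out;
}

// One barycenter refinement step: align the barycenter (always the first
// argument of the DTW alignment) with every series, pool per barycenter
// position the series elements its path pairs with that position, then
// replace the position by the pooled mean.  Boundary + continuity
// constraints guarantee every position receives at least one element
// per series, so counts are never zero.
// [[Rcpp::export]]
NumericVector cpp_dba_iteration(NumericVector center, List series) {
  const int l = center.size();
  std::vector<double> sum(l, 0.0);
  std::vector<int> cnt(l, 0);
  for (int j = 0; j < series.size(); ++j) {
    NumericVector t = as<NumericVector>(series[j]);
    const std::vector<double> D = acc_cost(center, t);
    std::vector<int> pi, pj;
    backtrack(D, l, t.size(), pi, pj);
    for (std::size_t k = 0; k < pi.size(); ++k) {
      sum[pi[k] - 1] += t[pj[k] - 1];
      cnt[pi[k] - 1] += 1;
    }
  }
  NumericVector out(l);
  for (int k = 0; k < l; ++k) out[k] = sum[k] / cnt[k];
  return out;
}
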