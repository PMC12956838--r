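#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming DTW between two sequences: local cost is the
// squared pointwise difference, unit steps (match / insert / delete),
// no warping window; the accumulated cost is square-rooted at the end.

// [[Rcpp::export]]
double dtw_distance_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}

// Optimal warping path (1-based index pairs), needed by barycenter
// averaging: for every barycenter position, which points of the series
// align to it.

// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  NumericMatrix D(n + 1, m + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = std::min(D(i - 1, j - 1),
                             std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = d * d + best;
    }
  }
  // backtrack
  std::vector<std::pair<int, int> > path;
  int i = n, j = m;
  path.push_back(std::make_pair(i, j));
  while (i > 1 || j > 1) {
    if (i == 1) {
      --j;
    } else if (j == 1) {
      --i;
    } else {
      double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    }
    path.push_back(std::make_pair(i, j));
  }
  IntegerMatrix out(path.size(), 2);
  for (size_t k = 0; k < path.size(); ++k) {
    out(path.size() - 1 - k, 0) = path[k].first;
    out(path.size() - 1 - k, 1) = path[k].second;
  }
  return out;
}

// One DTW barycenter-averaging update: align every series to the current
// centroid and replace each centroid point by the mean of all series
// points aligned to it.

// [[Rcpp::export]]
NumericVector dba_update_cpp(NumericVector centroid, List series) {
  int L = centroid.size();
  std::vector<double> sum(L, 0.0);
  std::vector<int> count(L, 0);
  for (int s = 0; s < series.size(); ++s) {
    NumericVector x = series[s];
    IntegerMatrix path = dtw_path_cpp(centroid, x);
    for (int k = 0; k < path.nrow(); ++k) {
      sum[path(k, 0) - 1] += x[path(k, 1) - 1];
      count[path(k, 0) - 1] += 1;
    }
  }
  NumericVector out(L);
  for (int i = 0; i < L; ++i) {
    out[i] = count[i] > 0 ? sum[i] / count[i] : centroid[i];
  }
  return out;
}
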