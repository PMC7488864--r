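#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Two-sample Kolmogorov-Smirnov statistic sup_t |F_x(t) - F_y(t)|.
// Hot loop of the correspondence bootstrap; inputs need not be sorted.
// [[Rcpp::export(name = ".ks_stat_cpp")]]
double ks_stat_cpp(NumericVector x, NumericVector y) {
  std::vector<double> sx(x.begin(), x.end());
  std::vector<double> sy(y.begin(), y.end());
  std::sort(sx.begin(), sx.end());
  std::sort(sy.begin(), sy.end());
  const double nx = sx.size(), ny = sy.size();
  size_t i = 0, j = 0;
  double d = 0.0, fx = 0.0, fy = 0.0;
  while (i < sx.size() && j < sy.size()) {
    double z = std::min(sx[i], sy[j]);
    while (i < sx.size() && sx[i] <= z) ++i;
    while (j < sy.size() && sy[j] <= z) ++j;
    fx = i / nx;
    fy = j / ny;
    double diff = std::fabs(fx - fy);
    if (diff > d) d = diff;
  }
  return d;
}

// Lower-triangle values of D[idx, idx] (1-based idx), i.e. the multiset of
// pairwise distances among the selected instances, without copying the
// submatrix.
// [[Rcpp::export(name = ".dist_subset_cpp")]]
NumericVector dist_subset_cpp(NumericMatrix D, IntegerVector idx) {
  const int n = idx.size();
  NumericVector out((double)n * (n - 1) / 2);
  int k = 0;
  for (int j = 0; j < n - 1; ++j) {
    const int cj = idx[j] - 1;
    for (int i = j + 1; i < n; ++i) {
      out[k++] = D(idx[i] - 1, cj);
    }
  }
  return out;
}
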