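#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Minimum-cost rectangular assignment (nr <= nc) by successive shortest
// augmenting paths with dual variables (Jonker-Volgenant style). Returns the
// 1-based column assigned to each row.
// [[Rcpp::export(name = ".lap_cpp")]]
IntegerVector lap_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr > nc) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(nr, 0.0), v(nc, 0.0), spc(nc);
  std::vector<int> row4col(nc, -1), col4row(nr, -1), path(nc, -1);
  std::vector<char> SR(nr), SC(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(spc.begin(), spc.end(), INF);
    double minVal = 0.0;
    int i = curRow, sink = -1;
    while (sink == -1) {
      SR[i] = 1;
      double lowest = INF;
      int jLow = -1;
      for (int j = 0; j < nc; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < spc[j]) { spc[j] = r; path[j] = i; }
        if (spc[j] < lowest || (spc[j] == lowest && jLow >= 0 &&
                                row4col[j] == -1 && row4col[jLow] != -1)) {
          lowest = spc[j];
          jLow = j;
        }
      }
      minVal = lowest;
      if (!std::isfinite(minVal)) stop("infeasible cost matrix");
      SC[jLow] = 1;
      if (row4col[jLow] == -1) sink = jLow; else i = row4col[jLow];
    }
    u[curRow] += minVal;
    for (int ii = 0; ii < nr; ++ii)
      if (SR[ii] && ii != curRow) u[ii] += minVal - spc[col4row[ii]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - spc[j];
    int j = sink;
    while (true) {
      int ii = path[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      j = tmp;
      if (ii == curRow) break;
    }
  }
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) out[r] = col4row[r] + 1;
  return out;
}

// KS statistic between the pairwise-distance multisets of P and P', where P'
// equals P with the rows at `changed_pos` (1-based positions into pidx)
// replaced by the rows `newidx` (1-based into D). Distances among unchanged
// rows cancel from both empirical cdfs, so only pairs touching a changed row
// are collected and sorted.
// [[Rcpp::export(name = ".sub_ks_cpp")]]
double sub_ks_cpp(NumericMatrix D, IntegerVector pidx, IntegerVector newidx,
                  IntegerVector changed_pos) {
  const int np = pidx.size(), k = changed_pos.size();
  std::vector<char> is_changed(np, 0);
  for (int t = 0; t < k; ++t) is_changed[changed_pos[t] - 1] = 1;

  std::vector<double> a, b;
  a.reserve((size_t)k * np);
  b.reserve((size_t)k * np);
  for (int t = 0; t < k; ++t) {
    const int pos = changed_pos[t] - 1;
    const int oi = pidx[pos] - 1, ni = newidx[t] - 1;
    for (int q = 0; q < np; ++q) {
      if (is_changed[q]) continue;
      a.push_back(D(oi, pidx[q] - 1));
      b.push_back(D(ni, pidx[q] - 1));
    }
    for (int s = t + 1; s < k; ++s) {
      const int pos2 = changed_pos[s] - 1;
      a.push_back(D(oi, pidx[pos2] - 1));
      b.push_back(D(ni, newidx[s] - 1));
    }
  }
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());

  const double npairs = (double)np * (np - 1) / 2.0;
  size_t i = 0, j = 0;
  double best = 0.0;
  while (i < a.size() || j < b.size()) {
    double v = INFINITY;
    if (i < a.size()) v = a[i];
    if (j < b.size() && b[j] < v) v = b[j];
    while (i < a.size() && a[i] <= v) ++i;
    while (j < b.size() && b[j] <= v) ++j;
    double diff = std::fabs((double)i - (double)j);
    if (diff > best) best = diff;
  }
  return best / npairs;
}
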