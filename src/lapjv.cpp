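#include <Rcpp.h>
#include <vector>
#include <limits>

// Optimal rectangular linear assignment by successive shortest augmenting
// paths with dual-variable (reduced cost) updates.  Requires nrow <= ncol;
// every row is assigned a distinct column minimizing total cost.  Scan order
// is fixed, so the result is deterministic for a given matrix.

// [[Rcpp::export]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr == 0 || nc == 0) Rcpp::stop("empty cost matrix");
  if (nr > nc) Rcpp::stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortest(nc);
  std::vector<int> col4row(nr, -1), row4col(nc, -1), path(nc), remaining(nc);
  std::vector<char> SR(nr), SC(nc);

  for (int currow = 0; currow < nr; ++currow) {
    double minVal = 0.0;
    int i = currow, sink = -1;
    int nrem = 0;
    for (int j = nc - 1; j >= 0; --j) remaining[nrem++] = j;
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(path.begin(), path.end(), -1);

    while (sink == -1) {
      SR[i] = 1;
      int index = -1;
      double lowest = INF;
      for (int it = 0; it < nrem; ++it) {
        const int j = remaining[it];
        const double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { path[j] = i; shortest[j] = r; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          index = it;
        }
      }
      minVal = lowest;
      if (minVal == INF) Rcpp::stop("infeasible cost matrix (non-finite entries?)");
      const int j = remaining[index];
      if (row4col[j] == -1) sink = j; else i = row4col[j];
      SC[j] = 1;
      remaining[index] = remaining[--nrem];
    }

    u[currow] += minVal;
    for (int k = 0; k < nr; ++k)
      if (SR[k] && k != currow) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    while (true) {
      const int ii = path[j];
      row4col[j] = ii;
      const int tmp = col4row[ii];
      col4row[ii] = j;
      if (ii == currow) break;
      j = tmp;
    }
  }

  Rcpp::IntegerVector out(nr);
  for (int k = 0; k < nr; ++k) out[k] = col4row[k] + 1;  // 1-based for R
  return out;
}
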