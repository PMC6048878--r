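#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact conditional p-value of the quadratic-form statistic
//   c(y) = (T - mu)' Sinv (T - mu),  T_k = sum_i g(i,k) * y_i
// by full enumeration of all distinct rearrangements of y
// (std::next_permutation over the sorted response; duplicated values are
// visited once each, which leaves the permutation proportion unchanged).
// Returns the proportion of rearrangements with statistic >= observed,
// within a small numerical tolerance.

// [[Rcpp::export]]
double perm_exact_pvalue(Rcpp::NumericMatrix g, Rcpp::NumericVector y,
                         Rcpp::NumericVector mu, Rcpp::NumericMatrix sinv,
                         double observed) {
  const int n = g.nrow(), q = g.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::sort(yy.begin(), yy.end());
  const double tol = 1e-9 * (1.0 + std::abs(observed));
  double count = 0.0, total = 0.0;
  std::vector<double> T(q);
  do {
    for (int k = 0; k < q; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += g(i, k) * yy[i];
      T[k] = s - mu[k];
    }
    double stat = 0.0;
    for (int k = 0; k < q; ++k)
      for (int l = 0; l < q; ++l) stat += T[k] * sinv(k, l) * T[l];
    if (stat >= observed - tol) count += 1.0;
    total += 1.0;
  } while (std::next_permutation(yy.begin(), yy.end()));
  return count / total;
}
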