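// Victor-Purpura spike-train edit distance: minimum total cost of turning
// one train into the other using insertion (cost 1), deletion (cost 1) and
// shifting a spike by t (cost q*t).  Standard O(n*m) dynamic program with a
// rolling row.

#include <Rcpp.h>
using namespace Rcpp;

static double vp_dp(const double* a, int n, const double* b, int m, double q) {
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double cpp_vp_distance(NumericVector a, NumericVector b, double q) {
  return vp_dp(a.begin(), a.size(), b.begin(), b.size(), q);
}

// [[Rcpp::export]]
NumericMatrix cpp_vp_matrix(List trains, double q) {
  int n = trains.size();
  std::vector<NumericVector> tr(n);
  for (int i = 0; i < n; ++i) tr[i] = as<NumericVector>(trains[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = vp_dp(tr[i].begin(), tr[i].size(), tr[j].begin(),
                       tr[j].size(), q);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}
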