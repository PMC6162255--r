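#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::sort(v.begin(), v.end());
  return (n % 2) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Per-row two-group statistics for a set of balanced relabelings.
//
// x: peptides x subjects matrix of log2 abundances (NA allowed).
// g1: B x k matrix of 1-based column indices forming group 1 for each
//     relabeling; group 2 is the complement.
// Returns per-row pooled-variance Student t (sign: group1 high => +) and
// the log2-median ratio (median group1 - median group2) for each
// relabeling. Rows with <2 observed values in either group get NA t;
// rows with <1 observed per group get NA ratio. Zero pooled variance
// yields t = 0 for equal means and signed infinity otherwise.
// [[Rcpp::export]]
List perm_stats_cpp(NumericMatrix x, IntegerMatrix g1) {
  const int m = x.nrow(), n = x.ncol(), B = g1.nrow(), k = g1.ncol();
  NumericMatrix tmat(m, B), rmat(m, B);
  std::vector<char> in1(n);
  std::vector<double> v1, v2;
  v1.reserve(n); v2.reserve(n);

  for (int b = 0; b < B; ++b) {
    std::fill(in1.begin(), in1.end(), 0);
    for (int j = 0; j < k; ++j) in1[g1(b, j) - 1] = 1;
    for (int i = 0; i < m; ++i) {
      v1.clear(); v2.clear();
      for (int c = 0; c < n; ++c) {
        const double v = x(i, c);
        if (ISNAN(v)) continue;
        if (in1[c]) v1.push_back(v); else v2.push_back(v);
      }
      const int n1 = (int)v1.size(), n2 = (int)v2.size();
      double t = NA_REAL, r = NA_REAL;
      if (n1 >= 2 && n2 >= 2) {
        double m1 = 0, m2 = 0;
        for (double v : v1) m1 += v;
        for (double v : v2) m2 += v;
        m1 /= n1; m2 /= n2;
        double ss = 0;
        for (double v : v1) ss += (v - m1) * (v - m1);
        for (double v : v2) ss += (v - m2) * (v - m2);
        const double sp2 = ss / (n1 + n2 - 2);
        if (sp2 <= 0) {
          t = (m1 == m2) ? 0.0 : (m1 > m2 ? R_PosInf : R_NegInf);
        } else {
          t = (m1 - m2) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n2));
        }
      }
      if (n1 >= 1 && n2 >= 1) r = median_of(v1) - median_of(v2);
      tmat(i, b) = t;
      rmat(i, b) = r;
    }
  }
  return List::create(_["t"] = tmat, _["ratio"] = rmat);
}
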