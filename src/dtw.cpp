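#include <Rcpp.h>
using namespace Rcpp;

// Full (unconstrained) dynamic time warping with squared local cost.
// Classic O(nm) dynamic program; symmetric step pattern (match, insert, delete).
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty segment");
  // rolling two-row DP to keep memory O(m)
  std::vector<double> prev(m), curr(m);
  for (int j = 0; j < m; ++j) {
    double d = a[0] - b[j];
    prev[j] = d * d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    double d0 = a[i] - b[0];
    curr[0] = d0 * d0 + prev[0];
    for (int j = 1; j < m; ++j) {
      double d = a[i] - b[j];
      double best = std::min(prev[j], std::min(prev[j - 1], curr[j - 1]));
      curr[j] = d * d + best;
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}

// DTW distances of many equal-length segments (rows) against one template.
// [[Rcpp::export(name = ".dtw_cost_many")]]
NumericVector dtw_cost_many(NumericMatrix segs, NumericVector tmpl) {
  const int k = segs.nrow();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    NumericVector row = segs(i, _);
    out[i] = dtw_cost(row, tmpl);
  }
  return out;
}
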