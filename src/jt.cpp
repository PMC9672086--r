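#include <Rcpp.h>
using namespace Rcpp;

// Raw Jonckheere-Terpstra statistic: sum over ordered group pairs i < j of
// Mann-Whitney counts, ties contributing 0.5. g holds 0-based group codes in
// the hypothesised ascending order.
static double jt_raw(const NumericVector& x, const IntegerVector& g) {
  const int n = x.size();
  double J = 0.0;
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      if (g[a] < g[b]) {
        if (x[a] < x[b]) J += 1.0;
        else if (x[a] == x[b]) J += 0.5;
      }
    }
  }
  return J;
}

// [[Rcpp::export]]
double jt_statistic_cpp(NumericVector x, IntegerVector g) {
  return jt_raw(x, g);
}

// Monte-Carlo relabelling: observations are shuffled across the fixed group
// layout (group sizes preserved). Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector jt_perm_cpp(NumericVector x, IntegerVector g, int n_perm) {
  const int n = x.size();
  NumericVector xs = clone(x);
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xs[i], xs[j]);
    }
    out[p] = jt_raw(xs, g);
  }
  return out;
}
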