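#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied independently to every
// column of X (time runs down the rows).  Coefficients follow the usual
// (b, a) convention with a[0] implicitly normalised to 1.
// [[Rcpp::export]]
NumericMatrix iir_filter_mat(NumericVector b, NumericVector a, NumericMatrix X) {
  int ord = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(ord + 1, 0.0), aa(ord + 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;

  int n = X.nrow(), m = X.ncol();
  NumericMatrix Y(n, m);
  std::vector<double> z(ord);
  for (int j = 0; j < m; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      double xt = X(t, j);
      double yt = bb[0] * xt + z[0];
      for (int k = 0; k < ord - 1; ++k)
        z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
      z[ord - 1] = bb[ord] * xt - aa[ord] * yt;
      Y(t, j) = yt;
    }
  }
  return Y;
}
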