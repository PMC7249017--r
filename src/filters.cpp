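#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// Coefficients must be normalised (a[0] == 1); zi has length
// max(len(a), len(b)) - 1 and is the filter state before the first sample.
// [[Rcpp::export]]
NumericVector df2t_filter(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int n = x.size();
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nz, 0.0);
  for (int i = 0; i < nz && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return y;
}
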