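#include <Rcpp.h>
using namespace Rcpp;

// Open (full) convolution of two probability mass vectors by direct
// summation. Direct accumulation of non-negative products preserves the
// *relative* accuracy of far-tail masses, which FFT-based convolution (whose
// error is absolute) would corrupt; those tails become the small P-values.
// [[Rcpp::export(name = ".conv_dense")]]
NumericVector conv_dense(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size(), m = b.size();
  NumericVector out(n + m - 1);
  for (R_xlen_t j = 0; j < m; ++j) {
    const double bj = b[j];
    if (bj == 0.0) continue;
    for (R_xlen_t i = 0; i < n; ++i) {
      out[i + j] += a[i] * bj;
    }
  }
  return out;
}
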