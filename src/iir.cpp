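#include <Rcpp.h>
using namespace Rcpp;

// Direct-form IIR filter (a[0] must be 1). Used for the noise-shaping and
// band-limiting filters of the synthetic EEG generator, where R-level
// recursive filtering dominates cohort synthesis time.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  const int n = x.size(), nb = b.size(), na = a.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const int jb = std::min(nb - 1, i);
    for (int j = 0; j <= jb; ++j) acc += b[j] * x[i - j];
    const int ja = std::min(na - 1, i);
    for (int j = 1; j <= ja; ++j) acc -= a[j] * y[i - j];
    y[i] = acc;
  }
  return y;
}
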