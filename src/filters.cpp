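#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// a[0] must be 1 (caller normalizes). State z has length n = max(na, nb) - 1.
// [[Rcpp::export(name = ".lfilter_cpp")]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int n = std::max(na, nb) - 1;
  std::vector<double> bb(n + 1, 0.0), aa(n + 1, 0.0), z(n, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  if (zi.size() == n) for (int i = 0; i < n; ++i) z[i] = zi[i];
  int N = x.size();
  NumericVector y(N);
  for (int m = 0; m < N; ++m) {
    double xm = x[m];
    double ym = bb[0] * xm + (n > 0 ? z[0] : 0.0);
    for (int i = 0; i < n - 1; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    if (n > 0) z[n - 1] = bb[n] * xm - aa[n] * ym;
    y[m] = ym;
  }
  return y;
}
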