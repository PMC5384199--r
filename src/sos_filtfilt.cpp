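#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering of matrix columns through a cascade of
// second-order sections (transposed direct-form II). Each section runs a
// forward pass then a backward pass over the column, so the net phase is
// zero. `sos` has one section per row: b0 b1 b2 a1 a2 (a0 normalized to
// 1). The column is zero-padded at the tail by `pad` samples to let the
// forward pass ring out before the backward pass; the pad is dropped.
// [[Rcpp::export]]
NumericMatrix sos_filtfilt_cpp(const NumericMatrix& x,
                               const NumericMatrix& sos, int pad) {
  const int n = x.nrow(), m = x.ncol(), ns = sos.nrow();
  const int N = n + pad;
  NumericMatrix out(n, m);
  std::vector<double> buf(N);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    std::fill(buf.begin() + n, buf.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 3), a2 = sos(s, 4);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < N; ++i) {
        const double xi = buf[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        buf[i] = yi;
      }
      z1 = z2 = 0.0;
      for (int i = N - 1; i >= 0; --i) {
        const double xi = buf[i];
        const double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        buf[i] = yi;
      }
    }
    for (int i = 0; i < n; ++i) out(i, j) = buf[i];
  }
  return out;
}
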