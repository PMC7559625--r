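#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR pass; b and a are pre-padded to nz + 1
// coefficients so the state update is branch-free.
static void iir_pass(const double* b, const double* a, const size_t nz,
                     std::vector<double>& x) {
  const size_t n = x.size();
  std::vector<double> z(nz + 1, 0.0);  // one spare slot so z[k] is valid
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (size_t k = 1; k <= nz; ++k) {
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    }
    z[nz] = 0.0;
    x[i] = yi;
  }
}

// Zero-phase (forward-backward) IIR filter; coefficients normalized by a[0].
// [[Rcpp::export]]
NumericVector iir_filtfilt_cpp(NumericVector b, NumericVector a,
                               NumericVector x) {
  const size_t nz = std::max(b.size(), a.size()) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  const double a0 = a[0];
  for (R_xlen_t k = 0; k < b.size(); ++k) bb[k] = b[k] / a0;
  for (R_xlen_t k = 0; k < a.size(); ++k) aa[k] = a[k] / a0;
  std::vector<double> w(x.begin(), x.end());
  iir_pass(bb.data(), aa.data(), nz, w);
  std::reverse(w.begin(), w.end());
  iir_pass(bb.data(), aa.data(), nz, w);
  std::reverse(w.begin(), w.end());
  return NumericVector(w.begin(), w.end());
}
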