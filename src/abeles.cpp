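// Abeles optical-matrix reflectivity kernel.
// Layers indexed fronting..backing; rho in 1e-6 A^-2; sigma[j] is the
// Nevot-Croce roughness of the interface between layer j-1 and j.
#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector abeles_kernel(NumericVector q, NumericVector d,
                            NumericVector rho, NumericVector sigma) {
  const int nq = q.size();
  const int m = rho.size();
  NumericVector out(nq);
  std::vector<std::complex<double> > k(m);
  const std::complex<double> I(0.0, 1.0);

  for (int iq = 0; iq < nq; ++iq) {
    const double kz0sq = q[iq] * q[iq] / 4.0;
    for (int j = 0; j < m; ++j) {
      // principal branch: evanescent regions get +i sqrt(|.|)
      k[j] = std::sqrt(std::complex<double>(
          kz0sq - 4.0 * M_PI * (rho[j] - rho[0]) * 1e-6, 0.0));
    }
    std::complex<double> M11(1.0, 0.0), M12(0.0, 0.0),
                         M21(0.0, 0.0), M22(1.0, 0.0);
    for (int j = 0; j < m - 1; ++j) {
      const std::complex<double> kj = k[j];
      const std::complex<double> kn = k[j + 1];
      const std::complex<double> r =
          (kj - kn) / (kj + kn) *
          std::exp(-2.0 * kj * kn * sigma[j + 1] * sigma[j + 1]);
      std::complex<double> ep(1.0, 0.0), en(1.0, 0.0);
      if (j > 0) {
        ep = std::exp(I * kj * d[j]);
        en = 1.0 / ep;
      }
      const std::complex<double> C11 = ep, C12 = r * ep;
      const std::complex<double> C21 = r * en, C22 = en;
      const std::complex<double> N11 = M11 * C11 + M12 * C21;
      const std::complex<double> N12 = M11 * C12 + M12 * C22;
      const std::complex<double> N21 = M21 * C11 + M22 * C21;
      const std::complex<double> N22 = M21 * C12 + M22 * C22;
      M11 = N11; M12 = N12; M21 = N21; M22 = N22;
    }
    double R = std::norm(M21 / M11);
    out[iq] = (R > 1.0 + 1e-12) ? 1.0 + 1e-12 : R;
  }
  return out;
}
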