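#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum Gaussian-enveloped echoes from point scatterers into an RF scanline
// matrix (fast-time sample x pulse). disp_m(s, j) is the displacement of
// scatterer s toward the probe at pulse j (m); the echo of a scatterer at
// depth d arrives at two-way delay 2 d / c. Envelopes are truncated at
// trunc_sigmas standard deviations.
// [[Rcpp::export]]
NumericMatrix rf_sim_kernel(NumericVector scat_depth_m, NumericVector refl,
                            NumericMatrix disp_m, int n_samples,
                            double fs, double fc, double c, double t0,
                            double sigma_t, double trunc_sigmas) {
  const int n_scat = scat_depth_m.size();
  const int n_pulses = disp_m.ncol();
  NumericMatrix rf(n_samples, n_pulses);
  const double two_pi_fc = 2.0 * M_PI * fc;
  const double half_width_s = trunc_sigmas * sigma_t;
  const double inv_two_sig2 = 0.5 / (sigma_t * sigma_t);
  for (int j = 0; j < n_pulses; ++j) {
    for (int s = 0; s < n_scat; ++s) {
      const double d = scat_depth_m[s] - disp_m(s, j);
      const double tau = 2.0 * d / c;
      int lo = (int)std::ceil(((tau - half_width_s) - t0) * fs);
      int hi = (int)std::floor(((tau + half_width_s) - t0) * fs);
      if (lo < 0) lo = 0;
      if (hi > n_samples - 1) hi = n_samples - 1;
      const double a = refl[s];
      for (int n = lo; n <= hi; ++n) {
        const double t = t0 + n / fs - tau;
        rf(n, j) += a * std::exp(-t * t * inv_two_sig2) *
          std::cos(two_pi_fc * t);
      }
    }
  }
  return rf;
}
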