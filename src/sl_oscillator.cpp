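#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Fixed-step exponential Euler-Maruyama integration of a forced
// Stuart-Landau oscillator:
//
//   dz/dt = (mu + i*omega - |z|^2) z + force(t) + noise
//
// The linear/nonlinear drift is applied through the exact exponential
// factor exp((mu - |z|^2 + i*omega) * dt) (|z|^2 frozen within the step),
// which keeps the deterministic limit-cycle radius at sqrt(mu) and the
// rotation rate at omega independent of dt. Forcing and the Wiener
// increments (supplied from R so that R's RNG/seed discipline applies)
// are added per step.
//
// z0re/z0im: initial condition; force: real forcing per sample (already
// multiplied by its gain); wre/wim: N(0,1) draws per sample; noise_amp:
// sigma * sqrt(dt).
// Charge-dependent coupling depletion: resource a in [0,1] with
//   da/dt = (1 - a)/tau_rec - a * |s(t)| / q_dep
// integrated with the exponential (exact per-step) update for the linear
// ODE with frozen |s|. Depletion engages only for drive above s_thresh
// (saturating stimuli); weak stimuli leave the coupling intact. Returns a(t) per sample; the effective forcing is
// a(t) * s(t).
// [[Rcpp::export(name = ".depletion_profile")]]
NumericVector depletion_profile(NumericVector s, double dt, double tau_rec,
                                double q_dep, double s_thresh) {
  int n = s.size();
  NumericVector a(n);
  double x = 1.0;
  for (int i = 0; i < n; ++i) {
    double drive = std::abs(s[i]) - s_thresh;
    if (drive < 0.0) drive = 0.0;
    double lam = 1.0 / tau_rec + drive / q_dep;
    double xinf = (1.0 / tau_rec) / lam;
    x = xinf + (x - xinf) * std::exp(-lam * dt);
    a[i] = x;
  }
  return a;
}

// [[Rcpp::export(name = ".sl_integrate")]]
NumericMatrix sl_integrate(int n, double dt, double mu, double omega,
                           double z0re, double z0im,
                           NumericVector force,
                           NumericVector wre, NumericVector wim,
                           double noise_amp) {
  NumericMatrix out(n, 2);
  std::complex<double> z(z0re, z0im);
  const std::complex<double> irot(0.0, omega);
  for (int i = 0; i < n; ++i) {
    double r2 = std::norm(z);
    std::complex<double> g = std::exp((std::complex<double>(mu - r2, 0.0) + irot) * dt);
    z = z * g + force[i] * dt + noise_amp * std::complex<double>(wre[i], wim[i]);
    out(i, 0) = z.real();
    out(i, 1) = z.imag();
  }
  return out;
}
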