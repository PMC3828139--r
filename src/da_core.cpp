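#include <Rcpp.h>
using namespace Rcpp;

// Integrators for the DA equation
//   tau_r * dR/dt = alpha_s * y(t) - (1 + beta * z(t)) * R(t)
// y, z are sampled on a uniform grid with step dt; R is returned on the
// same grid with R[0] = R0.

// Exponential-Euler update: over each step the filtered signals are taken
// at the step midpoint and held constant, for which the update is exact.
// Unconditionally stable; R relaxes to the local algebraic value
// alpha_s*y/(1+beta*z) when the effective time constant is short.
// [[Rcpp::export]]
NumericVector da_integrate_expeuler(NumericVector y, NumericVector z,
                                    double dt, double tau_r,
                                    double alpha_s, double beta, double R0) {
  int n = y.size();
  if (z.size() != n) stop("y and z must have equal length");
  NumericVector R(n);
  R[0] = R0;
  for (int k = 1; k < n; ++k) {
    double ym = 0.5 * (y[k - 1] + y[k]);
    double zm = 0.5 * (z[k - 1] + z[k]);
    double a = (1.0 + beta * zm) / tau_r;          // decay rate, 1/ms
    double rss = alpha_s * ym / (1.0 + beta * zm); // local fixed point
    double e = std::exp(-a * dt);
    R[k] = rss + (R[k - 1] - rss) * e;
  }
  return R;
}

// Direct evaluation of the exact solution
//   R(t) = (alpha_s/tau_r) * Int_{-inf}^{t} y(t')
//            exp( -(1/tau_r) Int_{t'}^{t} (1 + beta z(s)) ds ) dt'
// by incremental trapezoidal accumulation of both integrals (O(n)).
// [[Rcpp::export]]
NumericVector da_integrate_exact(NumericVector y, NumericVector z,
                                 double dt, double tau_r,
                                 double alpha_s, double beta, double R0) {
  int n = y.size();
  if (z.size() != n) stop("y and z must have equal length");
  NumericVector R(n);
  R[0] = R0;
  double c = alpha_s * dt / (2.0 * tau_r);
  for (int k = 1; k < n; ++k) {
    // exponent increment over [t_{k-1}, t_k], trapezoidal
    double ds = dt * (2.0 + beta * (z[k - 1] + z[k])) / (2.0 * tau_r);
    double e = std::exp(-ds);
    R[k] = R[k - 1] * e + c * (y[k] + y[k - 1] * e);
  }
  return R;
}

// First-order low-pass accumulator: u(t) = (1/tau) Int x(t') e^{-(t-t')/tau} dt'
// (trapezoidal), used for the linear beta = 0 limit and the small-flash
// perturbative response.
// [[Rcpp::export]]
NumericVector lin_lowpass(NumericVector x, double dt, double tau) {
  int n = x.size();
  NumericVector u(n);
  double e = std::exp(-dt / tau);
  double c = dt / (2.0 * tau);
  u[0] = 0.0;
  for (int k = 1; k < n; ++k)
    u[k] = u[k - 1] * e + c * (x[k] + x[k - 1] * e);
  return u;
}
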