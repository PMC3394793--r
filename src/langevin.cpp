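#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic 1-D potentials used by the synthetic pulling simulator.
// kind 0: harmonic      params = (a, x0)            V = a/2 (x-x0)^2
// kind 1: double_well   params = (h, c, x0)         V = h ((( x-x0)/c)^2 - 1)^2
// kind 2: gorge_profile params = (slope, A1,mu1,s1, A2,mu2,s2, ...)
//                       V = slope*x + sum_k Ak exp(-(x-muk)^2/(2 sk^2))
static inline double dVdx(const int kind, const NumericVector& p,
                          const double x) {
  switch (kind) {
  case 0:
    return p[0] * (x - p[1]);
  case 1: {
    const double u = (x - p[2]) / p[1];
    return 4.0 * p[0] * u * (u * u - 1.0) / p[1];
  }
  case 2: {
    double g = p[0];
    for (int k = 1; k + 2 <= p.size(); k += 3) {
      const double A = p[k], mu = p[k + 1], s = p[k + 2];
      const double z = (x - mu) / s;
      g += -A * z / s * std::exp(-0.5 * z * z);
    }
    return g;
  }
  default:
    stop("unknown potential kind");
  }
  return 0.0; // not reached
}

// Overdamped Euler-Maruyama integration of
//   dx = [-V'(x) + kappa (lambda(t) - x)] / gamma dt + sqrt(2 kT dt / gamma) dW
// lambda(t) = lambda0 + velocity * t.  Uses R's RNG (set.seed upstream).
// The switching work int kappa (lambda - x) dlambda is accumulated at the
// integration step (trapezoid in lambda), not at the coarser sampling
// stride, so work-exponential averages are free of quadrature noise.
// Returns a matrix with columns (time, xi, work) at the sampling stride,
// frame 0 included.
// [[Rcpp::export(name = ".simulate_langevin_cpp")]]
NumericMatrix simulate_langevin_cpp(int kind, NumericVector params,
                                    double x0, double lambda0,
                                    double velocity, double kappa,
                                    double duration, double dt,
                                    int sample_every, double gamma,
                                    double kT) {
  if (gamma <= 0 || dt <= 0 || duration <= 0 || sample_every < 1)
    stop("invalid Langevin parameters");
  const int nsteps = (int)std::lround(duration / dt);
  if (std::fabs(nsteps * dt - duration) > 1e-6 * duration)
    stop("dt must divide duration");
  const int nout = nsteps / sample_every + 1;
  NumericMatrix out(nout, 3);
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  const double dlam = velocity * dt;
  double x = x0;
  double work = 0.0;
  double f_prev = kappa * (lambda0 - x);
  out(0, 0) = 0.0;
  out(0, 1) = x;
  out(0, 2) = 0.0;
  int row = 1;
  RNGScope scope;
  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt;
    const double lam = lambda0 + velocity * t;
    const double F = -dVdx(kind, params, x) + kappa * (lam - x);
    x += F / gamma * dt + noise * norm_rand();
    const double f_cur = kappa * (lam + velocity * dt - x);
    work += 0.5 * (f_prev + f_cur) * dlam;
    f_prev = f_cur;
    if ((k + 1) % sample_every == 0) {
      out(row, 0) = (k + 1) * dt;
      out(row, 1) = x;
      out(row, 2) = work;
      ++row;
    }
  }
  return out;
}
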