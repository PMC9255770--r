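#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// First-passage-time density at the lower boundary of a zero-drift Wiener
// process with unit diffusion, unit boundary separation, relative start
// w in (0,1), at scaled time tau = t / A^2.  Small-time and large-time
// series; the cheaper representation is chosen from per-series error
// bounds at target eps (absolute, per term set).
static double fpt_scaled(const double tau, const double w, const double eps) {
  if (tau <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    if (ks < std::sqrt(tau) + 1.0) ks = std::sqrt(tau) + 1.0;
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    double lo = 1.0 / (M_PI * std::sqrt(tau));
    if (kl < lo) kl = lo;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = (K - 1) / 2 + ((K - 1) % 2);
    for (int k = lo; k <= hi; ++k) {
      double u = w + 2.0 * k;
      f += u * std::exp(-u * u / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Density of absorption at one bound at decision time t for a Wiener
// process with drift v, bounds at +a / -a, start x0 (between the bounds).
// upper = true gives the upper-bound (defective) density.
static double wfpt_one(const double t, const double v, const double a,
                       const double x0, const bool upper, const double eps) {
  if (t <= 0.0) return 0.0;
  const double A = 2.0 * a;
  // distance of start from the absorbing bound's opposite side, as a
  // fraction of separation; hitting the upper bound of (v, x0) equals
  // hitting the lower bound of (-v, -x0)
  double w = upper ? (a - x0) / A : (x0 + a) / A;
  double veff = upper ? -v : v;
  double g = fpt_scaled(t / (A * A), w, eps);
  return std::exp(-veff * A * w - v * v * t / 2.0) * g / (A * A);
}

// [[Rcpp::export]]
NumericMatrix wiener_fpt_density_cpp(NumericVector t, double d, double a,
                                     double z, double eps) {
  int n = t.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = wfpt_one(t[i], d, a, z, true, eps);
    out(i, 1) = wfpt_one(t[i], d, a, z, false, eps);
  }
  colnames(out) = CharacterVector::create("upper", "lower");
  return out;
}

// Defective density at decision time tau for one trial, averaging over
// uniform starting-point variability (Gauss-Legendre nodes glx on [-1,1],
// weights glw summing to 2) and Gaussian drift variability (Gauss-Hermite
// nodes ghx, weights ghw for weight function exp(-x^2)).
static double mixed_density(const double tau, const int choice,
                            const double drift, const double a,
                            const double z, const double sz, const double sd,
                            const NumericVector &ghx, const NumericVector &ghw,
                            const NumericVector &glx, const NumericVector &glw,
                            const double eps) {
  if (tau <= 0.0) return 0.0;
  const double A = 2.0 * a;
  const bool upper = choice > 0;
  const int nz = (sz > 0.0) ? glx.size() : 1;
  const int nv = (sd > 0.0) ? ghx.size() : 1;
  const double sqrt2 = std::sqrt(2.0), inv_sqrt_pi = 1.0 / std::sqrt(M_PI);

  double dens = 0.0;
  for (int j = 0; j < nz; ++j) {
    double x0 = (sz > 0.0) ? z + 0.5 * sz * glx[j] : z;
    double wz = (sz > 0.0) ? 0.5 * glw[j] : 1.0;
    double w = upper ? (a - x0) / A : (x0 + a) / A;
    if (w <= 0.0 || w >= 1.0) continue;  // start outside the bounds
    double g = fpt_scaled(tau / (A * A), w, eps) / (A * A);
    if (g <= 0.0) continue;
    for (int k = 0; k < nv; ++k) {
      double v = (sd > 0.0) ? drift + sqrt2 * sd * ghx[k] : drift;
      double wv = (sd > 0.0) ? ghw[k] * inv_sqrt_pi : 1.0;
      double veff = upper ? -v : v;
      dens += wz * wv * std::exp(-veff * A * w - v * v * tau / 2.0) * g;
    }
  }
  return dens;
}

// [[Rcpp::export]]
NumericVector defective_density_cpp(NumericVector rt, IntegerVector choice,
                                    NumericVector drift, NumericVector t0,
                                    double a, double z, double sz, double sd,
                                    NumericVector ghx, NumericVector ghw,
                                    NumericVector glx, NumericVector glw,
                                    double eps, double floor_val) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double dens = mixed_density(rt[i] - t0[i], choice[i], drift[i], a, z, sz,
                                sd, ghx, ghw, glx, glw, eps);
    out[i] = (dens > floor_val) ? dens : floor_val;
  }
  return out;
}

// [[Rcpp::export]]
double ddm_negloglik_cpp(NumericVector rt, IntegerVector choice,
                         NumericVector drift, NumericVector t0, double a,
                         double z, double sz, double sd, NumericVector ghx,
                         NumericVector ghw, NumericVector glx,
                         NumericVector glw, double eps, double floor_val) {
  int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double dens = mixed_density(rt[i] - t0[i], choice[i], drift[i], a, z, sz,
                                sd, ghx, ghw, glx, glw, eps);
    nll -= std::log((dens > floor_val) ? dens : floor_val);
  }
  return nll;
}

// Euler-Maruyama forward simulation; one path per element of drift.
// Discretely monitored paths systematically overshoot a continuous
// barrier, so the barriers are pulled inward by the Broadie-Glasserman-Kou
// continuity correction 0.5826 * sigma * sqrt(dt) (zeta(1/2)/sqrt(2*pi)).
// Uses R's RNG so results are reproducible under set.seed().
// choice: +1 upper bound, -1 lower bound, 0 censored at max_t.
// [[Rcpp::export]]
List ddm_simulate_cpp(NumericVector drift, double t0, double a, double z,
                      double sz, double sd, double dt, double max_t) {
  int n = drift.size();
  IntegerVector choice(n);
  NumericVector rt(n);
  const double sqdt = std::sqrt(dt);
  double ac = a - 0.5826 * sqdt;          // corrected barrier position
  if (ac < 0.5 * a) ac = 0.5 * a;         // guard for very coarse steps
  for (int i = 0; i < n; ++i) {
    double x = z + (sz > 0.0 ? sz * (unif_rand() - 0.5) : 0.0);
    double v = drift[i] + (sd > 0.0 ? sd * norm_rand() : 0.0);
    double t = 0.0;
    int ch = 0;
    if (x >= ac) ch = 1;                  // start beyond a corrected barrier
    else if (x <= -ac) ch = -1;
    else while (t < max_t) {
      x += v * dt + sqdt * norm_rand();
      t += dt;
      if (x >= ac) { ch = 1; break; }
      if (x <= -ac) { ch = -1; break; }
    }
    choice[i] = ch;
    rt[i] = t + t0;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
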