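// First-passage-time mathematics of the two-boundary Wiener diffusion
// (unit diffusion coefficient). Densities use the dual small-time /
// large-time series with adaptive truncation, picking whichever branch
// needs fewer terms for the requested error bound.

#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// Standardised lower-boundary FPT density at normalised time u = (t-tau)/a^2
// for zero drift, unit boundary separation, relative start w. Truncation error
// of the series is kept below eps.
double avddm_fpt_std(double u, double w, double eps) {
  if (u <= 0.0) return 0.0;
  if (eps < 1e-300) eps = 1e-300;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f = 0.0;
  if (ks < kl) {            // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1.0) / 2.0);
    int hi = (int)std::ceil((K - 1.0) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      f += wk * std::exp(-wk * wk / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {                  // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Joint density of absorbing at the chosen boundary at clock time t, for
// drift v, separation a, non-decision time tau, relative start w.
double avddm_wfpt_pdf(double t, int upper, double v, double a, double tau,
                      double w, double eps) {
  if (upper) { v = -v; w = 1.0 - w; }
  double dt = t - tau;
  if (dt <= 0.0) return 0.0;
  double u = dt / (a * a);
  double mult = std::exp(-v * a * w - v * v * dt / 2.0) / (a * a);
  double eps_std = eps;
  if (mult > 0.0 && std::isfinite(mult)) {
    eps_std = eps / mult;
    if (eps_std > 1e-3) eps_std = 1e-3;   // never coarser than this
    if (eps_std < 1e-300) eps_std = 1e-300;
  }
  return avddm_fpt_std(u, w, eps_std) * mult;
}

// Closed-form absorption probability at the upper boundary.
double avddm_p_upper(double v, double a, double w) {
  if (std::fabs(v) < 1e-10) return w;
  double q = -2.0 * v * a;
  if (q > 700.0) return std::exp(q * (w - 1.0));   // strong negative drift
  return std::expm1(q * w) / std::expm1(q);
}

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector t, IntegerVector upper, double delta,
                           double theta, double tau, double z, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = avddm_wfpt_pdf(t[i], upper[i % upper.size()], delta, theta, tau, z, eps);
  return out;
}

// [[Rcpp::export]]
double choice_prob_cpp(double delta, double theta, double z, int upper) {
  double p = avddm_p_upper(delta, theta, z);
  return upper ? p : 1.0 - p;
}

// Per-trial log joint density for arbitrary per-trial parameters; returns
// -Inf entries where rt <= tau.
// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector rt, IntegerVector upper,
                               NumericVector delta, NumericVector theta,
                               NumericVector tau, double z, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = avddm_wfpt_pdf(rt[i], upper[i], delta[i], theta[i], tau[i], z, eps);
    out[i] = f > 0.0 ? std::log(f) : R_NegInf;
  }
  return out;
}

// Exact sampler: inverse-CDF draw from the FPT distribution on an adaptive
// quadratically-spaced grid of normalised time (dense near zero where the
// density peaks under strong drift).
// [[Rcpp::export]]
List sim_wiener_cdf_cpp(int n, double delta, double theta, double tau,
                        double z, double eps, int grid_n = 20000) {
  const int N = grid_n;
  const double umax = 8.0;
  std::vector<double> u(N + 1), Fu(N + 1), Fl(N + 1);
  for (int j = 0; j <= N; ++j) {
    double s = (double)j / N;
    u[j] = umax * s * s;
  }
  // cumulative (trapezoid) of each boundary's density in normalised time
  double a2 = theta * theta;
  double fu_prev = 0.0, fl_prev = 0.0;
  Fu[0] = Fl[0] = 0.0;
  for (int j = 1; j <= N; ++j) {
    double tj = tau + u[j] * a2;
    double fu = avddm_wfpt_pdf(tj, 1, delta, theta, tau, z, eps) * a2;
    double fl = avddm_wfpt_pdf(tj, 0, delta, theta, tau, z, eps) * a2;
    double du = u[j] - u[j - 1];
    Fu[j] = Fu[j - 1] + 0.5 * (fu + fu_prev) * du;
    Fl[j] = Fl[j - 1] + 0.5 * (fl + fl_prev) * du;
    fu_prev = fu; fl_prev = fl;
  }
  double pu = avddm_p_upper(delta, theta, z);

  NumericVector rt(n);
  IntegerVector up(n);
  for (int i = 0; i < n; ++i) {
    int boundary = (unif_rand() < pu) ? 1 : 0;
    std::vector<double>& F = boundary ? Fu : Fl;
    double tot = F[N];
    double target = unif_rand() * tot;
    // binary search for the bracketing grid interval
    int lo = 0, hi = N;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (F[mid] < target) lo = mid; else hi = mid;
    }
    double frac = (F[hi] > F[lo]) ? (target - F[lo]) / (F[hi] - F[lo]) : 0.5;
    double uu = u[lo] + frac * (u[hi] - u[lo]);
    rt[i] = tau + uu * a2;
    up[i] = boundary;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}

// Euler-Maruyama path simulation with Brownian-bridge crossing correction
// between steps; independent of the series density above.
// [[Rcpp::export]]
List sim_wiener_em_cpp(int n, double delta, double theta, double tau,
                       double z, double dt) {
  NumericVector rt(n);
  IntegerVector up(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z * theta, t = 0.0;
    int boundary = -1;
    while (boundary < 0) {
      double xn = x + delta * dt + sdt * norm_rand();
      t += dt;
      if (xn >= theta) { boundary = 1; break; }
      if (xn <= 0.0)   { boundary = 0; break; }
      // bridge probability of an unseen crossing within the step
      double pu_br = std::exp(-2.0 * (theta - x) * (theta - xn) / dt);
      if (unif_rand() < pu_br) { boundary = 1; break; }
      double pl_br = std::exp(-2.0 * x * xn / dt);
      if (unif_rand() < pl_br) { boundary = 0; break; }
      x = xn;
      if (t > 1e4) { boundary = 1; break; }  // unreachable safety stop
    }
    rt[i] = tau + t;
    up[i] = boundary;
  }
  return List::create(_["rt"] = rt, _["upper"] = up);
}
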