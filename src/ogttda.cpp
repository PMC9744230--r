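// Compiled core: Cash-Karp embedded RK45 integration of the
// glucose-insulin-exocytosis system, the Gaussian OGTT log-posterior, and
// the random-walk Metropolis-Hastings chain.  Mirrors the R-level ode_rhs()
// exactly; the two routes are cross-checked in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Params {
  double S_I, sigma, gamma, E_G0, si_scale, k, V, beta, hepa_SI, r2_0;
  double cisr_max, K_half, K_slope, r2_base, r_unprime, r_undock,
         dock_base, dock_max;
  double hgp_max, I_half, h_pow;
  double dose_g, absorbed_fraction, glucose_vol_dl,
         appearance_shape, appearance_peak_min;
};

// layout must match params_for_cpp() on the R side
static Params params_from_vector(const NumericVector& v) {
  Params p;
  p.S_I = v[0];  p.sigma = v[1]; p.gamma = v[2]; p.E_G0 = v[3];
  p.si_scale = v[4]; p.k = v[5]; p.V = v[6]; p.beta = v[7];
  p.hepa_SI = v[8]; p.r2_0 = v[9];
  p.cisr_max = v[10]; p.K_half = v[11]; p.K_slope = v[12];
  p.r2_base = v[13]; p.r_unprime = v[14]; p.r_undock = v[15];
  p.dock_base = v[16]; p.dock_max = v[17];
  p.hgp_max = v[18]; p.I_half = v[19]; p.h_pow = v[20];
  p.dose_g = v[21]; p.absorbed_fraction = v[22]; p.glucose_vol_dl = v[23];
  p.appearance_shape = v[24]; p.appearance_peak_min = v[25];
  return p;
}

static inline double kappa_of(double G, const Params& p) {
  return 1.0 / (1.0 + std::exp(-(G - p.K_half * (1.0 + p.gamma)) / p.K_slope));
}

static inline double hgp_of(double I, const Params& p) {
  return p.hgp_max / (1.0 + p.hepa_SI * std::pow(I / p.I_half, p.h_pow));
}

static inline double flux_of(double t, const Params& p) {
  if (p.dose_g <= 0.0 || t <= 0.0) return 0.0;
  double shape = p.appearance_shape;
  double scale = p.appearance_peak_min / (shape - 1.0);
  double total = p.dose_g * 1000.0 * p.absorbed_fraction / p.glucose_vol_dl;
  return total * std::pow(t, shape - 1.0) * std::exp(-t / scale) /
         (std::tgamma(shape) * std::pow(scale, shape));
}

static void rhs(double t, const double y[4], double dy[4], const Params& p) {
  double G = y[0], I = y[1], N5 = y[2], N6 = y[3];
  double kap = kappa_of(G, p);
  double C_ISR = p.cisr_max * kap;
  double r2 = p.r2_0 * (p.r2_base + kap);
  double c55 = -(C_ISR + p.r_unprime);
  double c56 = r2;
  double c65 = p.r_unprime;
  double c66 = -(r2 + p.r_undock);
  double c60 = p.sigma * (p.dock_base + p.dock_max * kap);
  dy[0] = flux_of(t, p) + hgp_of(I, p) - (p.E_G0 + p.si_scale * p.S_I * I) * G;
  dy[1] = (p.beta / p.V) * C_ISR * N5 - p.k * I;
  dy[2] = c55 * N5 + c56 * N6;
  dy[3] = c60 + c65 * N5 + c66 * N6;
}

// Cash-Karp RK45 coefficients
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}
};
static const double CK_C5[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0, 512.0/1771};
static const double CK_C4[6] = {2825.0/27648, 0, 18575.0/48384, 13525.0/55296,
                                277.0/14336, 1.0/4};

// integrate from t0 to t1 in place; returns false on failure
static bool integrate(double t0, double t1, double y[4], const Params& p,
                      double rtol = 1e-6, double atol = 1e-8) {
  double t = t0, h = std::min(1.0, t1 - t0);
  double k[6][4], ytmp[4], y5[4], err[4];
  int nstep = 0;
  while (t < t1 - 1e-12) {
    if (++nstep > 100000) return false;
    if (t + h > t1) h = t1 - t;
    rhs(t, y, k[0], p);
    for (int s = 1; s < 6; ++s) {
      static const double A[6] = {0, 1.0/5, 3.0/10, 3.0/5, 1.0, 7.0/8};
      for (int i = 0; i < 4; ++i) {
        double acc = 0;
        for (int j = 0; j < s; ++j) acc += CK_B[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      rhs(t + A[s] * h, ytmp, k[s], p);
    }
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      double s5 = 0, s4 = 0;
      for (int j = 0; j < 6; ++j) { s5 += CK_C5[j] * k[j][i]; s4 += CK_C4[j] * k[j][i]; }
      y5[i] = y[i] + h * s5;
      err[i] = h * (s5 - s4);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      errmax = std::max(errmax, std::fabs(err[i]) / sc);
    }
    if (!std::isfinite(errmax)) return false;
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
      if (h < 1e-8) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix simulate_rk45_cpp(NumericVector params, NumericVector init,
                                NumericVector times) {
  Params p = params_from_vector(params);
  double y[4] = {init[0], init[1], init[2], init[3]};
  int n = times.size();
  NumericMatrix out(n, 4);
  double t = times[0];
  if (t != 0.0) stop("times must start at 0 for the compiled integrator");
  for (int i = 0; i < n; ++i) {
    if (times[i] > t) {
      if (!integrate(t, times[i], y, p))
        stop("integration failure near t = %f", times[i]);
      t = times[i];
    }
    for (int j = 0; j < 4; ++j) out(i, j) = y[j];
  }
  return out;
}

// fasting steady state of (I, N5, N6) at glucose G, with HGP re-anchoring;
// returns {G, I, N5, N6, hgp_max}
static bool steady_state(double G, Params& p, double out[4]) {
  double kap = kappa_of(G, p);
  double C_ISR = p.cisr_max * kap;
  double r2 = p.r2_0 * (p.r2_base + kap);
  double c55 = -(C_ISR + p.r_unprime);
  double c66 = -(r2 + p.r_undock);
  double c60 = p.sigma * (p.dock_base + p.dock_max * kap);
  double ratio = -r2 / c55;
  double denom = -(c66 + p.r_unprime * ratio);
  if (!(denom > 0) || !std::isfinite(denom)) return false;
  double N6 = c60 / denom;
  double N5 = ratio * N6;
  double I = (p.beta / (p.V * p.k)) * C_ISR * N5;
  double clearance = (p.E_G0 + p.si_scale * p.S_I * I) * G;
  p.hgp_max = clearance * (1.0 + p.hepa_SI * std::pow(I / p.I_half, p.h_pow));
  out[0] = G; out[1] = I; out[2] = N5; out[3] = N6;
  return true;
}

// [[Rcpp::export]]
NumericVector steady_state_cpp(NumericVector params, double G_fast) {
  Params p = params_from_vector(params);
  double st[4];
  if (!steady_state(G_fast, p, st)) stop("no admissible fasting steady state");
  return NumericVector::create(st[0], st[1], st[2], st[3], p.hgp_max);
}

static double log_post_impl(double S_I, double sigma, Params p,
                            const NumericVector& t_obs,
                            const NumericVector& g_obs,
                            const NumericVector& i_obs, bool use_insulin,
                            double sd_g, const NumericVector& sd_i,
                            double I0, double lo_si, double hi_si,
                            double lo_sg, double hi_sg) {
  if (S_I < lo_si || S_I > hi_si || sigma < lo_sg || sigma > hi_sg)
    return R_NegInf;
  p.S_I = S_I; p.sigma = sigma;
  double y[4];
  if (!steady_state(g_obs[0], p, y)) return R_NegInf;
  if (I0 >= 0.0) y[1] = I0;   // measured I_0 (or the fixed fallback)
  double lp = 0.0, t = t_obs[0];
  for (int i = 0; i < t_obs.size(); ++i) {
    if (t_obs[i] > t) {
      if (!integrate(t, t_obs[i], y, p)) return R_NegInf;
      t = t_obs[i];
    }
    double rg = g_obs[i] - y[0];
    lp += -0.5 * std::log(2.0 * M_PI * sd_g * sd_g) - rg * rg / (2.0 * sd_g * sd_g);
    if (use_insulin) {
      double s = sd_i[i];
      double ri = i_obs[i] - y[1];
      lp += -0.5 * std::log(2.0 * M_PI * s * s) - ri * ri / (2.0 * s * s);
    }
  }
  return std::isfinite(lp) ? lp : R_NegInf;
}

// [[Rcpp::export]]
double log_posterior_cpp(NumericVector theta, NumericVector params,
                         NumericVector t_obs, NumericVector g_obs,
                         NumericVector i_obs, bool use_insulin,
                         double sd_g, NumericVector sd_i, double I0,
                         NumericVector bounds_SI, NumericVector bounds_sigma) {
  Params p = params_from_vector(params);
  return log_post_impl(theta[0], theta[1], p, t_obs, g_obs, i_obs, use_insulin,
                       sd_g, sd_i, I0, bounds_SI[0], bounds_SI[1],
                       bounds_sigma[0], bounds_sigma[1]);
}

// Random-walk Metropolis-Hastings with joint diagonal-Gaussian proposals.
// Proposal scales adapt every 500 iterations during burn-in toward the
// 0.2-0.5 acceptance band, then freeze.  Uses R's RNG (seeded from R).
// [[Rcpp::export]]
List rwmh_cpp(NumericVector params, NumericVector t_obs, NumericVector g_obs,
              NumericVector i_obs, bool use_insulin, double sd_g,
              NumericVector sd_i, double I0, NumericVector bounds_SI,
              NumericVector bounds_sigma, int n_iter, int burn_in,
              NumericVector prop_sd, bool adapt) {
  Params p = params_from_vector(params);
  double lo1 = bounds_SI[0], hi1 = bounds_SI[1];
  double lo2 = bounds_sigma[0], hi2 = bounds_sigma[1];
  double th1 = 0.5 * (lo1 + hi1), th2 = 0.5 * (lo2 + hi2);
  double s1 = prop_sd[0], s2 = prop_sd[1];
  double lp = log_post_impl(th1, th2, p, t_obs, g_obs, i_obs, use_insulin,
                            sd_g, sd_i, I0, lo1, hi1, lo2, hi2);
  NumericMatrix samples(n_iter, 2);
  NumericVector lptrace(n_iter);
  int acc_post = 0, acc_win = 0, win = 0;
  for (int it = 0; it < n_iter; ++it) {
    double c1 = th1 + R::rnorm(0.0, s1);
    double c2 = th2 + R::rnorm(0.0, s2);
    double lp_new = log_post_impl(c1, c2, p, t_obs, g_obs, i_obs, use_insulin,
                                  sd_g, sd_i, I0, lo1, hi1, lo2, hi2);
    bool accept = std::log(R::runif(0.0, 1.0)) < (lp_new - lp);
    if (accept) { th1 = c1; th2 = c2; lp = lp_new; }
    samples(it, 0) = th1;
    samples(it, 1) = th2;
    lptrace[it] = lp;
    if (it >= burn_in) acc_post += accept;
    else if (adapt) {
      acc_win += accept; ++win;
      if (win == 500) {
        double rate = acc_win / 500.0;
        if (rate < 0.2) { s1 *= 0.8; s2 *= 0.8; }
        else if (rate > 0.5) { s1 *= 1.25; s2 *= 1.25; }
        acc_win = 0; win = 0;
      }
    }
  }
  int n_post = n_iter - burn_in;
  return List::create(
    _["samples"] = samples,
    _["log_posterior"] = lptrace,
    _["acceptance_rate"] = n_post > 0 ? (double)acc_post / n_post : NA_REAL,
    _["proposal_sd"] = NumericVector::create(s1, s2));
}
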