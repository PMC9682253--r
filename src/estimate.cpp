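#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-stage MAP estimation of (t1, Delta) from the first N-1 spike times.
//
// For a fixed candidate interval Delta, write a_i = s_i - (i-1) Delta.
// The log-likelihood in t is sum_i [ (n-1) log(a_i - t) - (a_i - t)/tau_I ]
// on the causal region t <= min_i a_i. It is strictly concave in t, so the
// inner problem has a unique optimum:
//   n == 1 : the log-likelihood increases in t, optimum on the boundary
//            t* = min_i a_i;
//   n  > 1 : interior root of sum_i 1/(a_i - t) = m / ((n-1) tau_I), found
//            by Newton iteration started below the root (the stationarity
//            function is increasing and convex, so the iteration ascends
//            monotonically without overshooting).
// The outer problem over Delta is a profile search on a log-spaced grid
// with successive zoom stages around the running optimum.

struct ObsConsts {
  double tau_I, n_shape, tau_Delta, sigma;
  bool prior_on;
  double log_tau_I, lgamma_n;
};

static double profile_obj(const std::vector<double>& s, double delta,
                          const ObsConsts& c, double* t_out) {
  const int m = (int)s.size();
  double a[64];
  double tmax = R_PosInf;
  for (int i = 0; i < m; ++i) {
    a[i] = s[i] - i * delta;
    if (a[i] < tmax) tmax = a[i];
  }
  double tstar;
  if (c.n_shape <= 1.0) {
    tstar = tmax;
  } else {
    const double target = m / ((c.n_shape - 1.0) * c.tau_I);
    double t = tmax - (c.n_shape - 1.0) * c.tau_I;
    for (int it = 0; it < 30; ++it) {
      double h = -target, hp = 0.0;
      for (int i = 0; i < m; ++i) {
        double inv = 1.0 / (a[i] - t);
        h += inv;
        hp += inv * inv;
      }
      double tn = t - h / hp;
      if (tn >= tmax) tn = 0.5 * (t + tmax);
      double moved = std::fabs(tn - t);
      t = tn;
      if (moved < 1e-13) break;
    }
    tstar = t;
  }
  double ll = -m * (c.n_shape * c.log_tau_I + c.lgamma_n);
  for (int i = 0; i < m; ++i) {
    double lag = a[i] - tstar;
    if (c.n_shape > 1.0) {
      if (lag <= 0.0) return R_NegInf;
      ll += (c.n_shape - 1.0) * std::log(lag);
    }
    ll -= lag / c.tau_I;
  }
  if (c.prior_on) {
    double z = std::log(delta / c.tau_Delta);
    ll += -std::log(delta) - std::log(c.sigma) - M_LN_SQRT_2PI
          - z * z / (2.0 * c.sigma * c.sigma);
  }
  *t_out = tstar;
  return ll;
}

// [[Rcpp::export(name = ".estimate_map_cpp")]]
List estimate_map_cpp(NumericMatrix spikes, double tau_I, double n_shape,
                      double tau_Delta, double sigma, bool prior_on,
                      double lo, double hi, int n_coarse, int n_zoom,
                      int n_stages) {
  const int n_trials = spikes.nrow();
  const int m = spikes.ncol();
  if (m < 2) stop("need at least two spikes per trial");
  if (m > 64) stop("too many spikes per trial");
  if (!(hi > lo) || lo <= 0.0) stop("invalid interval search range");
  if (n_coarse < 4 || n_zoom < 4) stop("grid sizes too small");

  ObsConsts c;
  c.tau_I = tau_I; c.n_shape = n_shape; c.tau_Delta = tau_Delta;
  c.sigma = sigma; c.prior_on = prior_on;
  c.log_tau_I = std::log(tau_I);
  c.lgamma_n = R::lgammafn(n_shape);

  NumericVector t1(n_trials), delta(n_trials), logpost(n_trials);
  std::vector<double> s(m);
  const double llo = std::log(lo), lhi = std::log(hi);
  const double step0 = (lhi - llo) / (n_coarse - 1);

  for (int tr = 0; tr < n_trials; ++tr) {
    for (int i = 0; i < m; ++i) s[i] = spikes(tr, i);

    double best_ll = R_NegInf, best_ld = llo, best_t = NA_REAL;
    for (int g = 0; g < n_coarse; ++g) {
      double ld = llo + g * step0;
      double tcur;
      double ll = profile_obj(s, std::exp(ld), c, &tcur);
      if (ll > best_ll) { best_ll = ll; best_ld = ld; best_t = tcur; }
    }
    double span = step0;
    for (int stage = 0; stage < n_stages; ++stage) {
      double start = best_ld - span;
      double step = 2.0 * span / (n_zoom - 1);
      double c_best_ld = best_ld;
      for (int g = 0; g < n_zoom; ++g) {
        double ld = start + g * step;
        if (ld < llo) ld = llo;
        if (ld > lhi) ld = lhi;
        double tcur;
        double ll = profile_obj(s, std::exp(ld), c, &tcur);
        if (ll > best_ll) { best_ll = ll; c_best_ld = ld; best_t = tcur; }
      }
      best_ld = c_best_ld;
      span = step;
    }
    t1[tr] = best_t;
    delta[tr] = std::exp(best_ld);
    logpost[tr] = best_ll;
  }
  return List::create(_["t1_est"] = t1, _["delta_est"] = delta,
                      _["log_posterior"] = logpost);
}
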