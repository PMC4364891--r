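// Adaptive Metropolis-within-Gibbs sampler for the joint hierarchical
// distance-sampling model:
//   distances   x_j ~ HalfNormal(sigma_j),  sigma_j = sqrt(2/pi) * w_j,
//               w_j = exp(a0 + a1 b_j + a2 scov_j + eps0_j)
//   group sizes s_j ~ Pois(lambda_s) (whale; optionally zero-truncated)
//               or logN(mu_s, sigma_s^2) (dolphin)
//   counts      n_i ~ Pois(lambda_i),
//               lambda_i = 2 w_i L_i d_i g0 / meansize,
//               w_i = exp(a0 + a1 B_i + a2 M + eps1_i),
//               d_i = exp(poly(A_i) + eps2_i)   (or the model average)
// Globals are updated univariately by random-walk MH, recomputing only the
// posterior components each parameter touches; the three random-effect
// blocks are updated elementwise with local likelihoods.  Proposal scales
// adapt toward 0.44 acceptance during burn-in only.  All randomness comes
// from R's RNG, so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG2 = 0.6931471805599453;
static const double LOG_2PI = 1.8378770664093453;
static const double SQRT_2_OVER_PI = 0.7978845608028654;

struct Model {
  // cell data
  NumericVector L, B, A;   // effort km, effort-weighted Beaufort, scaled ADT
  IntegerVector n;         // group counts
  // sighting data
  NumericVector x, b, scov, s;  // perp dist, Beaufort, size covariate, size
  bool whale;
  bool zt;                 // zero-truncated Poisson group sizes
  int hform;               // 0 poly2, 1 poly3, 2 average
  double g0a, g0b;         // Beta prior shapes
  double trunc;            // right-truncation distance (<=0: none)
  int I, J;
  double s_sum, s_lgam, slog_sum, slog2_sum;  // group-size sufficient stats
  // global layout
  int idx_gs, n_gs, idx_hab, n_hab, nglob;

  Model(List data, bool whale_, bool zt_, int hform_, double g0a_,
        double g0b_, double trunc_)
    : whale(whale_), zt(zt_), hform(hform_), g0a(g0a_), g0b(g0b_),
      trunc(trunc_) {
    L = data["L"]; B = data["B"]; A = data["A"]; n = data["n"];
    x = data["x"]; b = data["b"]; scov = data["scov"]; s = data["s"];
    I = L.size(); J = x.size();
    s_sum = s_lgam = slog_sum = slog2_sum = 0.0;
    for (int j = 0; j < J; ++j) {
      s_sum += s[j];
      s_lgam += R::lgammafn(s[j] + 1.0);
      double ls = std::log(s[j]);
      slog_sum += ls;
      slog2_sum += ls * ls;
    }
    idx_gs = 7;
    n_gs = whale ? 1 : 2;
    idx_hab = idx_gs + n_gs;
    n_hab = hform == 0 ? 3 : (hform == 1 ? 4 : 8);
    nglob = idx_hab + n_hab;
  }

  double size_cov_mean(const NumericVector& g) const {
    // cell-level group-size covariate, on the sighting-model scale
    return whale ? g[idx_gs] : g[idx_gs] + 0.5 * g[idx_gs + 1] * g[idx_gs + 1];
  }
  double mean_size(const NumericVector& g) const {
    // arithmetic mean group size (individuals), the density divisor
    return whale ? g[idx_gs] : std::exp(g[idx_gs] +
                                        0.5 * g[idx_gs + 1] * g[idx_gs + 1]);
  }

  double ll_dist_one(double xj, double bj, double scj, double e0,
                     const NumericVector& g) const {
    double sig = SQRT_2_OVER_PI *
      std::exp(g[0] + g[1] * bj + g[2] * scj + e0);
    double ll = LOG2 + R::dnorm(xj, 0.0, sig, 1);
    if (trunc > 0.0)
      ll -= std::log(2.0 * R::pnorm(trunc / sig, 0.0, 1.0, 1, 0) - 1.0);
    return ll;
  }

  double ll_dist(const NumericVector& g, const NumericVector& eps0) const {
    double t = 0.0;
    for (int j = 0; j < J; ++j)
      t += ll_dist_one(x[j], b[j], scov[j], eps0[j], g);
    return t;
  }

  double ll_size(const NumericVector& g) const {
    if (J == 0) return 0.0;
    if (whale) {
      double lam = g[idx_gs];
      double t = s_sum * std::log(lam) - J * lam - s_lgam;
      if (zt) t -= J * std::log(1.0 - std::exp(-lam));
      return t;
    }
    double mu = g[idx_gs], sd = g[idx_gs + 1];
    return -slog_sum - J * std::log(sd) - 0.5 * J * LOG_2PI -
      (slog2_sum - 2.0 * mu * slog_sum + J * mu * mu) / (2.0 * sd * sd);
  }

  // Poisson mean of every cell's group count
  void lambda_all(const NumericVector& g, const NumericVector& eps1,
                  const NumericVector& eps2, std::vector<double>& lam) const {
    double M = size_cov_mean(g), ms = mean_size(g), g0 = g[6];
    for (int i = 0; i < I; ++i) {
      double w = std::exp(g[0] + g[1] * B[i] + g[2] * M + eps1[i]);
      double a = A[i], d;
      if (hform == 0) {
        d = std::exp(g[idx_hab] + g[idx_hab + 1] * a +
                     g[idx_hab + 2] * a * a + eps2[i]);
      } else if (hform == 1) {
        d = std::exp(g[idx_hab] + g[idx_hab + 1] * a +
                     g[idx_hab + 2] * a * a + g[idx_hab + 3] * a * a * a +
                     eps2[i]);
      } else {
        double q2 = g[idx_hab] + g[idx_hab + 1] * a + g[idx_hab + 2] * a * a;
        double q3 = g[idx_hab + 3] + g[idx_hab + 4] * a +
          g[idx_hab + 5] * a * a + g[idx_hab + 6] * a * a * a;
        double vt = g[idx_hab + 7];
        d = std::exp(eps2[i]) * (vt * std::exp(q2) +
                                 (1.0 - vt) * std::exp(q3));
      }
      lam[i] = 2.0 * w * L[i] * d * g0 / ms;
    }
  }

  static double ll_pois(double n, double lam) {
    if (lam <= 0.0) return n > 0 ? -1e10 : 0.0;
    return n * std::log(lam) - lam - R::lgammafn(n + 1.0);
  }

  double ll_count_from(const std::vector<double>& lam) const {
    double t = 0.0;
    for (int i = 0; i < I; ++i) t += ll_pois((double)n[i], lam[i]);
    return t;
  }

  bool in_bounds(int k, double v) const {
    if (k == 3 || k == 4 || k == 5) return v > 0.0 && v < 10.0;     // RE SDs
    if (k == 6) return v > 0.0 && v < 1.0;                           // g0
    if (whale && k == idx_gs) return v > 0.0 && v < 1000.0;          // lambda_s
    if (!whale && k == idx_gs + 1) return v > 0.0 && v < 10.0;       // sigma_s
    if (hform == 2 && k == idx_hab + 7) return v >= 0.0 && v <= 1.0; // vartheta
    return std::isfinite(v);
  }

  // log prior of the globals, excluding flat (uniform) factors
  double log_prior(const NumericVector& g) const {
    double t = 0.0;
    t += R::dnorm(g[0], 0.0, 100.0, 1) + R::dnorm(g[1], 0.0, 100.0, 1) +
      R::dnorm(g[2], 0.0, 100.0, 1);
    t += R::dbeta(g[6], g0a, g0b, 1);
    if (!whale) t += R::dnorm(g[idx_gs], 0.0, 100.0, 1);  // mu_s
    int ncoef = hform == 2 ? 7 : n_hab;                   // vartheta uniform
    for (int k = 0; k < ncoef; ++k)
      t += R::dnorm(g[idx_hab + k], 0.0, 100.0, 1);
    return t;
  }

  static double lp_re(const NumericVector& e, double sd) {
    double t = 0.0;
    for (int k = 0; k < e.size(); ++k) t += R::dnorm(e[k], 0.0, sd, 1);
    return t;
  }

  // which components parameter k touches
  bool touches_dist(int k) const { return k <= 2; }
  bool touches_size(int k) const {
    return k >= idx_gs && k < idx_gs + n_gs;
  }
  bool touches_count(int k) const {
    return k <= 2 || k == 6 || (k >= idx_gs && k < nglob);
  }
  bool is_re_sd(int k) const { return k >= 3 && k <= 5; }
};

// [[Rcpp::export(name = ".run_chain")]]
List run_chain(List data, bool whale, bool zt, int hform, double g0a,
               double g0b, double trunc, NumericVector init, int n_iter,
               int n_burn, int thin, NumericVector prop_sd_init,
               double re_prop_sd_init) {
  RNGScope scope;
  Model mod(data, whale, zt, hform, g0a, g0b, trunc);
  const int nglob = mod.nglob, I = mod.I, J = mod.J;
  if (init.size() != nglob) stop("bad init length");

  NumericVector g = clone(init);
  NumericVector eps0(J), eps1(I), eps2(I);
  std::vector<double> lam(I), lam_prop(I);

  NumericVector psd = clone(prop_sd_init);
  double psd_e0 = re_prop_sd_init, psd_e1 = re_prop_sd_init,
    psd_e2 = re_prop_sd_init;

  // cached posterior components
  double D = mod.ll_dist(g, eps0);
  double S = mod.ll_size(g);
  mod.lambda_all(g, eps1, eps2, lam);
  double C = mod.ll_count_from(lam);
  double P = mod.log_prior(g);
  double R0 = Model::lp_re(eps0, g[3]);
  double R1 = Model::lp_re(eps1, g[4]);
  double R2 = Model::lp_re(eps2, g[5]);
  if (!std::isfinite(D + S + C + P))
    stop("initial state has non-finite posterior");

  int n_ret = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_ret, nglob), lam_draws(n_ret, I);
  NumericMatrix e0_draws(n_ret, J), e1_draws(n_ret, I), e2_draws(n_ret, I);
  NumericVector dev(n_ret);

  std::vector<int> acc(nglob, 0), try_(nglob, 0);
  int acc_e0 = 0, try_e0 = 0, acc_e1 = 0, try_e1 = 0, acc_e2 = 0, try_e2 = 0;
  int batch = 0, ret = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- univariate MH on globals ---
    for (int k = 0; k < nglob; ++k) {
      ++try_[k];
      double old = g[k];
      double prop = old + norm_rand() * psd[k];
      if (!mod.in_bounds(k, prop)) continue;
      g[k] = prop;
      if (mod.is_re_sd(k)) {
        // only the matching random-effect prior changes
        double Rnew = k == 3 ? Model::lp_re(eps0, prop)
          : k == 4 ? Model::lp_re(eps1, prop) : Model::lp_re(eps2, prop);
        double Rold = k == 3 ? R0 : (k == 4 ? R1 : R2);
        if (std::log(unif_rand()) < Rnew - Rold) {
          (k == 3 ? R0 : k == 4 ? R1 : R2) = Rnew;
          ++acc[k];
        } else {
          g[k] = old;
        }
        continue;
      }
      double Dn = mod.touches_dist(k) ? mod.ll_dist(g, eps0) : D;
      double Sn = mod.touches_size(k) ? mod.ll_size(g) : S;
      double Cn = C;
      bool cnt = mod.touches_count(k);
      if (cnt) {
        mod.lambda_all(g, eps1, eps2, lam_prop);
        Cn = mod.ll_count_from(lam_prop);
      }
      double Pn = mod.log_prior(g);
      double delta = (Dn - D) + (Sn - S) + (Cn - C) + (Pn - P);
      if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
        D = Dn; S = Sn; C = Cn; P = Pn;
        if (cnt) lam.swap(lam_prop);
        ++acc[k];
      } else {
        g[k] = old;
      }
    }

    // --- elementwise MH on sighting residuals eps0 ---
    for (int j = 0; j < J; ++j) {
      ++try_e0;
      double old = eps0[j];
      double prop = old + norm_rand() * psd_e0;
      double dD = mod.ll_dist_one(mod.x[j], mod.b[j], mod.scov[j], prop, g) -
        mod.ll_dist_one(mod.x[j], mod.b[j], mod.scov[j], old, g);
      double dR = R::dnorm(prop, 0.0, g[3], 1) - R::dnorm(old, 0.0, g[3], 1);
      if (std::log(unif_rand()) < dD + dR) {
        eps0[j] = prop; D += dD; R0 += dR; ++acc_e0;
      }
    }

    // --- elementwise MH on cell residuals eps1 then eps2 ---
    // lambda_i depends on each residual through a factor exp(eps)
    for (int rb = 0; rb < 2; ++rb) {
      NumericVector& e = rb == 0 ? eps1 : eps2;
      double sd_re = rb == 0 ? g[4] : g[5];
      double& psd_e = rb == 0 ? psd_e1 : psd_e2;
      int& acc_e = rb == 0 ? acc_e1 : acc_e2;
      int& try_e = rb == 0 ? try_e1 : try_e2;
      for (int i = 0; i < I; ++i) {
        ++try_e;
        double old = e[i];
        double prop = old + norm_rand() * psd_e;
        double lam_new = lam[i] * std::exp(prop - old);
        double dC = Model::ll_pois((double)mod.n[i], lam_new) -
          Model::ll_pois((double)mod.n[i], lam[i]);
        double dR = R::dnorm(prop, 0.0, sd_re, 1) -
          R::dnorm(old, 0.0, sd_re, 1);
        if (std::log(unif_rand()) < dC + dR) {
          e[i] = prop; lam[i] = lam_new;
          C += dC;
          (rb == 0 ? R1 : R2) += dR;
          ++acc_e;
        }
      }
    }

    // --- adaptation during burn-in ---
    if (it <= n_burn && it % 50 == 0) {
      ++batch;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int k = 0; k < nglob; ++k) {
        double rate = try_[k] ? (double)acc[k] / try_[k] : 0.0;
        psd[k] *= std::exp(rate > 0.44 ? step : -step);
        acc[k] = 0; try_[k] = 0;
      }
      double r0 = try_e0 ? (double)acc_e0 / try_e0 : 0.0;
      double r1 = try_e1 ? (double)acc_e1 / try_e1 : 0.0;
      double r2 = try_e2 ? (double)acc_e2 / try_e2 : 0.0;
      psd_e0 *= std::exp(r0 > 0.44 ? step : -step);
      psd_e1 *= std::exp(r1 > 0.44 ? step : -step);
      psd_e2 *= std::exp(r2 > 0.44 ? step : -step);
      acc_e0 = try_e0 = acc_e1 = try_e1 = acc_e2 = try_e2 = 0;
    }

    // --- refresh caches periodically to stop numerical drift ---
    if (it % 500 == 0) {
      D = mod.ll_dist(g, eps0);
      S = mod.ll_size(g);
      mod.lambda_all(g, eps1, eps2, lam);
      C = mod.ll_count_from(lam);
      P = mod.log_prior(g);
      R0 = Model::lp_re(eps0, g[3]);
      R1 = Model::lp_re(eps1, g[4]);
      R2 = Model::lp_re(eps2, g[5]);
    }

    // --- retain ---
    if (it > n_burn && (it - n_burn) % thin == 0 && ret < n_ret) {
      for (int k = 0; k < nglob; ++k) draws(ret, k) = g[k];
      for (int i = 0; i < I; ++i) {
        lam_draws(ret, i) = lam[i];
        e1_draws(ret, i) = eps1[i];
        e2_draws(ret, i) = eps2[i];
      }
      for (int j = 0; j < J; ++j) e0_draws(ret, j) = eps0[j];
      dev[ret] = -2.0 * (mod.ll_dist(g, eps0) + mod.ll_size(g) +
                         mod.ll_count_from(lam));
      ++ret;
    }
  }

  NumericVector acc_rate(nglob);
  for (int k = 0; k < nglob; ++k)
    acc_rate[k] = try_[k] ? (double)acc[k] / try_[k] : NA_REAL;

  return List::create(_["globals"] = draws, _["lambda"] = lam_draws,
                      _["eps0"] = e0_draws, _["eps1"] = e1_draws,
                      _["eps2"] = e2_draws, _["deviance"] = dev,
                      _["accept"] = acc_rate, _["prop_sd"] = psd);
}
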