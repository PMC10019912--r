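// Metropolis-within-Gibbs sampler for the single-visit Dail-Madsen
// open-population N-mixture model with latent integer abundances and an
// optional measurement-error model on imputed sampling effort.
//
// Latent state per site i, year t: N[i,t] with N[i,t] = S[i,t] + R[i,t]
// for t >= 2, S[i,t] <= N[i,t-1]. Counts X (NA encoded as -1) enter via
// X[i,t] ~ Binomial(N[i,t], p[i,t]) at surveyed cells only.
//
// Parameter vector theta (length 18):
//   0..4   beta_lambda (log link, initial abundance; covariates at year 1)
//   5..9   beta_omega  (logit link, survival)
//   10..14 beta_gamma  (log link, recruitment)
//   15..17 alpha = (a0, a_e > 0, a_m < 0) (logit link, detection)
//
// Binomial/Poisson log-densities are evaluated through a cached
// log-factorial table plus cached log-rate matrices, which is what makes
// per-cell latent updates cheap enough for desk-scale chains.
//
// Uses R's RNG throughout, so set.seed() in R gives reproducible chains.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(n!) table, grown on demand
static std::vector<double> lgt_tab;
static inline double lgt(int n) {
  if (n < 0) return NEG_INF;
  if ((size_t)n >= lgt_tab.size()) {
    size_t old = lgt_tab.size();
    size_t nw = std::max((size_t)(n + 1) * 2, (size_t)4096);
    lgt_tab.resize(nw);
    if (old == 0) { lgt_tab[0] = 0.0; old = 1; }
    for (size_t k = old; k < nw; ++k)
      lgt_tab[k] = lgt_tab[k - 1] + std::log((double)k);
  }
  return lgt_tab[n];
}

static inline double dbinom_fast(int x, int n, double logp, double log1mp) {
  if (x < 0 || x > n) return NEG_INF;
  return lgt(n) - lgt(x) - lgt(n - x) + x * logp + (n - x) * log1mp;
}
static inline double dpois_fast(int x, double lambda, double loglambda) {
  if (x < 0) return NEG_INF;
  if (lambda <= 0) return (x == 0) ? 0.0 : NEG_INF;
  return x * loglambda - lambda - lgt(x);
}

struct DMMState {
  int I, T;
  IntegerMatrix X;          // -1 = not surveyed
  NumericVector Z;          // I x T x 4 standardized covariates
  NumericMatrix effort;     // standardized effort (latent where sdE > 0)
  NumericMatrix effort_hat; // centre of the effort measurement prior
  NumericMatrix sdE;        // measurement-error sd (0 = known effort)
  NumericMatrix temp;       // standardized minimum temperature
  NumericVector theta;
  LogicalVector update;
  double prior_sd;
  IntegerMatrix N, S, R;
  // cached rates and their logs
  std::vector<double> lam, llam;
  NumericMatrix om, lom, l1mom;      // valid for t >= 1
  NumericMatrix ga, lga;
  NumericMatrix p, lpr, l1mpr;

  double zc(int i, int t, int j) const { return Z[i + I * (t + T * j)]; }

  static double clip_prob(double x) {
    return std::min(std::max(x, 1e-9), 1.0 - 1e-9);
  }
  double omega_at(int i, int t, const double *b) const {
    double e = b[0] + b[1] * zc(i, t, 0) + b[2] * zc(i, t, 1) +
               b[3] * zc(i, t, 2) + b[4] * zc(i, t, 3);
    return clip_prob(1.0 / (1.0 + std::exp(-e)));
  }
  double gamma_at(int i, int t, const double *b) const {
    double e = b[0] + b[1] * zc(i, t, 0) + b[2] * zc(i, t, 1) +
               b[3] * zc(i, t, 2) + b[4] * zc(i, t, 3);
    return std::max(std::exp(e), 1e-9);
  }
  double lambda_at(int i, const double *b) const {
    double e = b[0] + b[1] * zc(i, 0, 0) + b[2] * zc(i, 0, 1) +
               b[3] * zc(i, 0, 2) + b[4] * zc(i, 0, 3);
    return std::max(std::exp(e), 1e-9);
  }
  double p_at(int i, int t, const double *a, double eff) const {
    double e = a[0] + a[1] * eff + a[2] * temp(i, t);
    return clip_prob(1.0 / (1.0 + std::exp(-e)));
  }

  void recompute_lam() {
    for (int i = 0; i < I; ++i) {
      lam[i] = lambda_at(i, &theta[0]);
      llam[i] = std::log(lam[i]);
    }
  }
  void recompute_om() {
    for (int i = 0; i < I; ++i)
      for (int t = 1; t < T; ++t) {
        double w = omega_at(i, t, &theta[5]);
        om(i, t) = w; lom(i, t) = std::log(w); l1mom(i, t) = std::log1p(-w);
      }
  }
  void recompute_ga() {
    for (int i = 0; i < I; ++i)
      for (int t = 1; t < T; ++t) {
        double g = gamma_at(i, t, &theta[10]);
        ga(i, t) = g; lga(i, t) = std::log(g);
      }
  }
  void set_p(int i, int t, double pv) {
    p(i, t) = pv; lpr(i, t) = std::log(pv); l1mpr(i, t) = std::log1p(-pv);
  }
  void recompute_p() {
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < T; ++t) set_p(i, t, p_at(i, t, &theta[15], effort(i, t)));
  }

  // block log-likelihoods at candidate coefficients
  double ll_init(const double *b) const {
    double ll = 0;
    for (int i = 0; i < I; ++i) {
      double la = lambda_at(i, b);
      ll += dpois_fast(N(i, 0), la, std::log(la));
    }
    return ll;
  }
  double ll_surv(const double *b) const {
    double ll = 0;
    for (int i = 0; i < I; ++i)
      for (int t = 1; t < T; ++t) {
        double w = omega_at(i, t, b);
        ll += dbinom_fast(S(i, t), N(i, t - 1), std::log(w), std::log1p(-w));
      }
    return ll;
  }
  double ll_rec(const double *b) const {
    double ll = 0;
    for (int i = 0; i < I; ++i)
      for (int t = 1; t < T; ++t) {
        double g = gamma_at(i, t, b) * N(i, t - 1);
        ll += dpois_fast(R(i, t), g, g > 0 ? std::log(g) : 0.0);
      }
    return ll;
  }
  double ll_obs(const double *a) const {
    double ll = 0;
    for (int i = 0; i < I; ++i)
      for (int t = 0; t < T; ++t)
        if (X(i, t) >= 0) {
          double pv = p_at(i, t, a, effort(i, t));
          ll += dbinom_fast(X(i, t), N(i, t), std::log(pv), std::log1p(-pv));
        }
    return ll;
  }
  double ll_all() const {
    return ll_init(&theta[0]) + ll_surv(&theta[5]) + ll_rec(&theta[10]) +
           ll_obs(&theta[15]);
  }
  // mode of the survivor-allocation conditional f(s) = Bin(s; np, om) *
  // Pois(nt - s; ga*np), located by binary search on the monotone
  // probability ratio (f is log-concave)
  static int alloc_mode(int np, int nt, double lom_, double l1mom_,
                        double lgaN) {
    int smax = std::min(np, nt);
    int lo_b = 0, hi_b = smax;
    while (lo_b < hi_b) {
      int mid = (lo_b + hi_b + 1) / 2;
      double lr = lom_ - l1mom_ + std::log((double)(np - mid + 1)) -
                  std::log((double)mid) +
                  std::log((double)(nt - mid + 1)) - lgaN;
      if (lr >= 0) lo_b = mid; else hi_b = mid - 1;
    }
    return lo_b;
  }

  // log of the S-marginalized transition probability P(N_t = nt | np),
  // summed over a window around the allocation mode (truncating tail
  // mass beyond ~4 sd + 10)
  static double ll_trans_marginal(int np, int nt, double om_, double ga_) {
    if (np < 0 || nt < 0) return NEG_INF;
    if (np == 0) return (nt == 0) ? 0.0 : NEG_INF;
    double lom_ = std::log(om_), l1mom_ = std::log1p(-om_);
    double grate = ga_ * np;
    double lgaN = std::log(grate);
    int smax = std::min(np, nt);
    int mode = alloc_mode(np, nt, lom_, l1mom_, lgaN);
    int W = std::min(256, 10 + (int)(4.0 * std::sqrt(np * om_ * (1.0 - om_) + 1.0)));
    int wlo = std::max(0, mode - W), whi = std::min(smax, mode + W);
    double mx = NEG_INF;
    static std::vector<double> w;
    w.assign(whi - wlo + 1, 0.0);
    for (int sc = wlo; sc <= whi; ++sc) {
      double lw = dbinom_fast(sc, np, lom_, l1mom_) +
                  dpois_fast(nt - sc, grate, lgaN);
      w[sc - wlo] = lw;
      if (lw > mx) mx = lw;
    }
    if (mx == NEG_INF) return NEG_INF;
    double tot = 0;
    for (size_t j2 = 0; j2 < w.size(); ++j2) tot += std::exp(w[j2] - mx);
    return mx + std::log(tot);
  }

  // total S/R-marginalized demographic log-likelihood at candidate
  // survival/recruitment coefficients
  double ll_demog_marginal(const double *bo, const double *bg) const {
    double ll = 0;
    for (int i = 0; i < I; ++i)
      for (int t = 1; t < T; ++t) {
        ll += ll_trans_marginal(N(i, t - 1), N(i, t), omega_at(i, t, bo),
                                gamma_at(i, t, bg));
        if (ll == NEG_INF) return NEG_INF;
      }
    return ll;
  }

  // draw the survivor allocation from its windowed conditional at the
  // current rates, for every transition cell
  void redraw_alloc_site(int i) {
    for (int t = 1; t < T; ++t) {
        int np = N(i, t - 1), nt = N(i, t);
        if (np == 0 || nt == 0) { S(i, t) = 0; R(i, t) = nt; continue; }
        double lgaN = lga(i, t) + std::log((double)np);
        double grate = ga(i, t) * np;
        int smax = std::min(np, nt);
        int mode = alloc_mode(np, nt, lom(i, t), l1mom(i, t), lgaN);
        int W = std::min(256, 10 + (int)(4.0 * std::sqrt(np * om(i, t) * (1.0 - om(i, t)) + 1.0)));
        int wlo = std::max(0, mode - W), whi = std::min(smax, mode + W);
        int len = whi - wlo + 1;
        static std::vector<double> w;
        w.assign(len, 0.0);
        double mx = NEG_INF;
        for (int sc = wlo; sc <= whi; ++sc) {
          double lw = dbinom_fast(sc, np, lom(i, t), l1mom(i, t)) +
                      dpois_fast(nt - sc, grate, lgaN);
          w[sc - wlo] = lw;
          if (lw > mx) mx = lw;
        }
        double tot = 0;
        for (int j2 = 0; j2 < len; ++j2) { w[j2] = std::exp(w[j2] - mx); tot += w[j2]; }
        double u = unif_rand() * tot, csum = 0;
        int snew = whi;
        for (int j2 = 0; j2 < len; ++j2) {
          csum += w[j2];
          if (u <= csum) { snew = wlo + j2; break; }
        }
        S(i, t) = snew; R(i, t) = nt - snew;
      }
  }
  void redraw_alloc() {
    for (int i = 0; i < I; ++i) redraw_alloc_site(i);
  }

  double log_prior(const NumericVector &th) const {
    if (th[16] <= 0 || th[17] >= 0) return NEG_INF; // a_e > 0, a_m < 0
    double lp0 = 0;
    for (int j = 0; j < 18; ++j)
      if (update[j]) lp0 += R::dnorm(th[j], 0.0, prior_sd, 1);
    return lp0;
  }
};

static inline int rw_step(int jump) {
  int mag = 1 + (int)(unif_rand() * jump);
  if (mag > jump) mag = jump;
  return (unif_rand() < 0.5) ? -mag : mag;
}

// local log-lik around N(i,0)
static double ll_local_N1(DMMState &st, int i, int n1) {
  if (n1 < 0) return NEG_INF;
  double ll = dpois_fast(n1, st.lam[i], st.llam[i]);
  if (st.X(i, 0) >= 0) {
    if (st.X(i, 0) > n1) return NEG_INF;
    ll += dbinom_fast(st.X(i, 0), n1, st.lpr(i, 0), st.l1mpr(i, 0));
  }
  if (st.T > 1) {
    if (st.S(i, 1) > n1) return NEG_INF;
    ll += dbinom_fast(st.S(i, 1), n1, st.lom(i, 1), st.l1mom(i, 1));
    double g = st.ga(i, 1) * n1;
    ll += dpois_fast(st.R(i, 1), g, n1 > 0 ? st.lga(i, 1) + std::log((double)n1) : 0.0);
  }
  return ll;
}

// local log-lik for (S,R) at (i,t), t >= 1, with N(i,t) = S + R
static double ll_local_t(DMMState &st, int i, int t, int s, int r) {
  int nprev = st.N(i, t - 1);
  if (s < 0 || r < 0 || s > nprev) return NEG_INF;
  int n = s + r;
  double grate = st.ga(i, t) * nprev;
  double ll = dbinom_fast(s, nprev, st.lom(i, t), st.l1mom(i, t)) +
              dpois_fast(r, grate,
                         nprev > 0 ? st.lga(i, t) + std::log((double)nprev) : 0.0);
  if (st.X(i, t) >= 0) {
    if (st.X(i, t) > n) return NEG_INF;
    ll += dbinom_fast(st.X(i, t), n, st.lpr(i, t), st.l1mpr(i, t));
  }
  if (t + 1 < st.T) {
    if (st.S(i, t + 1) > n) return NEG_INF;
    ll += dbinom_fast(st.S(i, t + 1), n, st.lom(i, t + 1), st.l1mom(i, t + 1));
    double g2 = st.ga(i, t + 1) * n;
    ll += dpois_fast(st.R(i, t + 1), g2,
                     n > 0 ? st.lga(i, t + 1) + std::log((double)n) : 0.0);
  }
  return ll;
}

// site log-likelihood with the whole trajectory shifted by d, with the
// survivor/recruit allocation summed out of every transition: only the
// initial-abundance, marginal transition, and observation terms remain,
// so the move is not blocked by the current allocation
static double ll_site_shift_marginal(DMMState &st, int i, int d) {
  int n1 = st.N(i, 0) + d;
  if (n1 < 0) return NEG_INF;
  double ll = dpois_fast(n1, st.lam[i], st.llam[i]);
  if (st.X(i, 0) >= 0) {
    if (st.X(i, 0) > n1) return NEG_INF;
    ll += dbinom_fast(st.X(i, 0), n1, st.lpr(i, 0), st.l1mpr(i, 0));
  }
  for (int t = 1; t < st.T; ++t) {
    int nprev = st.N(i, t - 1) + d, n = st.N(i, t) + d;
    ll += DMMState::ll_trans_marginal(nprev, n, st.om(i, t), st.ga(i, t));
    if (ll == NEG_INF) return NEG_INF;
    if (st.X(i, t) >= 0) {
      if (st.X(i, t) > n) return NEG_INF;
      ll += dbinom_fast(st.X(i, t), n, st.lpr(i, t), st.l1mpr(i, t));
    }
  }
  return ll;
}

// whole-trajectory level shift per site: the direction most strongly
// coupled to the detection intercept. Accepted against the
// allocation-marginalized likelihood; the allocation is redrawn from its
// conditional on acceptance (same collapsed-MH pattern as the
// survival/recruitment block move).
static void update_shift_marginal(DMMState &st, const IntegerVector &jumps,
                                  double *acc, double *tries) {
  for (int i = 0; i < st.I; ++i) {
    int dshift = rw_step(jumps[i]);
    tries[0] += 1;
    double dll = ll_site_shift_marginal(st, i, dshift) -
                 ll_site_shift_marginal(st, i, 0);
    if (dll > NEG_INF && (dll >= 0 || unif_rand() < std::exp(dll))) {
      for (int t = 0; t < st.T; ++t) st.N(i, t) += dshift;
      st.redraw_alloc_site(i);
      acc[0] += 1;
    }
  }
}

static void update_latent(DMMState &st, const IntegerVector &jumps,
                          bool do_gibbs, double *acc, double *tries) {
  for (int i = 0; i < st.I; ++i) {
    int jump = jumps[i];
    int cur = st.N(i, 0);
    int prop = cur + rw_step(jump);
    tries[0] += 1;
    if (prop >= 0) {
      double d = ll_local_N1(st, i, prop) - ll_local_N1(st, i, cur);
      if (d >= 0 || unif_rand() < std::exp(d)) { st.N(i, 0) = prop; acc[0] += 1; }
    }
    for (int t = 1; t < st.T; ++t) {
      int s = st.S(i, t), r = st.R(i, t);
      double ll0 = ll_local_t(st, i, t, s, r);
      int sp = s + rw_step(jump);                    // move survivors
      tries[1] += 1;
      double ll1 = ll_local_t(st, i, t, sp, r);
      if (ll1 > NEG_INF &&
          (ll1 - ll0 >= 0 || unif_rand() < std::exp(ll1 - ll0))) {
        s = sp; st.S(i, t) = s; st.N(i, t) = s + r; acc[1] += 1;
        ll0 = ll1;
      }
      int rp = r + rw_step(jump);                    // move recruits
      tries[1] += 1;
      ll1 = ll_local_t(st, i, t, s, rp);
      if (ll1 > NEG_INF &&
          (ll1 - ll0 >= 0 || unif_rand() < std::exp(ll1 - ll0))) {
        r = rp; st.R(i, t) = r; st.N(i, t) = s + r; acc[1] += 1;
        ll0 = ll1;
      }
      // reallocate survivors vs recruits at fixed N_t. The conditional of
      // S given everything else involves only the binomial survival term
      // and the Poisson recruitment term and is log-concave, so we draw
      // it (near-)exactly from a window around its mode -- located by
      // binary search on the monotone probability ratio -- truncating
      // tail mass beyond ~4 sd + 10 (comparable to the model's other
      // truncations). Falls back to a wide swap walk if the current
      // state sits outside the window.
      if (do_gibbs) {
        int n_t = s + r, nprev = st.N(i, t - 1);
        int smax = std::min(nprev, n_t);
        double om_ = st.om(i, t), ga_ = st.ga(i, t);
        double lgaN = nprev > 0 ? st.lga(i, t) + std::log((double)nprev) : 0.0;
        double grate = ga_ * nprev;
        // mode: largest sc with f(sc)/f(sc-1) >= 1
        int lo_b = 0, hi_b = smax;
        while (lo_b < hi_b) {
          int mid = (lo_b + hi_b + 1) / 2;
          // ratio f(mid)/f(mid-1)
          double lr = st.lom(i, t) - st.l1mom(i, t) +
                      std::log((double)(nprev - mid + 1)) -
                      std::log((double)mid) +
                      std::log((double)(n_t - mid + 1)) - lgaN;
          if (lr >= 0) lo_b = mid; else hi_b = mid - 1;
        }
        int mode = lo_b;
        int W = std::min(256, 10 + (int)(4.0 * std::sqrt(nprev * om_ * (1.0 - om_) + 1.0)));
        int wlo = std::max(0, mode - W), whi = std::min(smax, mode + W);
        if (s >= wlo && s <= whi) {
          int len = whi - wlo + 1;
          static std::vector<double> w;
          w.assign(len, 0.0);
          double mx = NEG_INF;
          for (int sc = wlo; sc <= whi; ++sc) {
            double lw = dbinom_fast(sc, nprev, st.lom(i, t), st.l1mom(i, t)) +
                        dpois_fast(n_t - sc, grate, lgaN);
            w[sc - wlo] = lw;
            if (lw > mx) mx = lw;
          }
          double tot = 0;
          for (int j2 = 0; j2 < len; ++j2) { w[j2] = std::exp(w[j2] - mx); tot += w[j2]; }
          double u = unif_rand() * tot, csum = 0;
          int snew = whi;
          for (int j2 = 0; j2 < len; ++j2) {
            csum += w[j2];
            if (u <= csum) { snew = wlo + j2; break; }
          }
          st.S(i, t) = snew; st.R(i, t) = n_t - snew;
          tries[1] += 1; acc[1] += 1;
          continue;
        }
      }
      int d = rw_step(std::max(jump, (int)std::sqrt((double)(s + r)) / 2));
      tries[1] += 1;
      ll1 = ll_local_t(st, i, t, s + d, r - d);
      if (ll1 > NEG_INF &&
          (ll1 - ll0 >= 0 || unif_rand() < std::exp(ll1 - ll0))) {
        s += d; r -= d; st.S(i, t) = s; st.R(i, t) = r; acc[1] += 1;
      }
    }
  }
}

static void update_effort(DMMState &st, double step, double *acc,
                          double *tries) {
  for (int i = 0; i < st.I; ++i)
    for (int t = 0; t < st.T; ++t) {
      if (st.sdE(i, t) <= 0 || st.X(i, t) < 0) continue;
      double cur = st.effort(i, t);
      double prop = cur + norm_rand() * step * st.sdE(i, t);
      double pp = st.p_at(i, t, &st.theta[15], prop);
      double d =
          dbinom_fast(st.X(i, t), st.N(i, t), std::log(pp), std::log1p(-pp)) -
          dbinom_fast(st.X(i, t), st.N(i, t), st.lpr(i, t), st.l1mpr(i, t)) +
          R::dnorm(prop, st.effort_hat(i, t), st.sdE(i, t), 1) -
          R::dnorm(cur, st.effort_hat(i, t), st.sdE(i, t), 1);
      tries[0] += 1;
      if (d >= 0 || unif_rand() < std::exp(d)) {
        st.effort(i, t) = prop;
        st.set_p(i, t, pp);
        acc[0] += 1;
      }
    }
}

static double block_ll(DMMState &st, int j, const double *cand) {
  if (j < 5) return st.ll_init(cand);
  if (j < 10) return st.ll_surv(cand);
  if (j < 15) return st.ll_rec(cand);
  return st.ll_obs(cand);
}

static void update_theta_univariate(DMMState &st, std::vector<double> &scales,
                                    std::vector<double> &acc,
                                    std::vector<double> &tries) {
  double cand[5];
  for (int j = 0; j < 18; ++j) {
    if (!st.update[j]) continue;
    int off = (j < 5) ? 0 : (j < 10) ? 5 : (j < 15) ? 10 : 15;
    int len = (j < 15) ? 5 : 3;
    for (int k = 0; k < len; ++k) cand[k] = st.theta[off + k];
    double cur = st.theta[j];
    double prop = cur + norm_rand() * scales[j];
    tries[j] += 1;
    if ((j == 16 && prop <= 0) || (j == 17 && prop >= 0)) continue;
    cand[j - off] = prop;
    double d = block_ll(st, j, cand) - block_ll(st, j, &st.theta[off]) +
               R::dnorm(prop, 0.0, st.prior_sd, 1) -
               R::dnorm(cur, 0.0, st.prior_sd, 1);
    if (d >= 0 || unif_rand() < std::exp(d)) {
      st.theta[j] = prop;
      acc[j] += 1;
      if (j < 5) st.recompute_lam();
      else if (j < 10) st.recompute_om();
      else if (j < 15) st.recompute_ga();
      else st.recompute_p();
    }
  }
}

// lower-triangular Cholesky of a small SPD matrix
static bool chol_lower(const std::vector<double> &A, int n,
                       std::vector<double> &L) {
  L.assign(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= L[i * n + k] * L[j * n + k];
      if (i == j) {
        if (s <= 0) return false;
        L[i * n + i] = std::sqrt(s);
      } else {
        L[i * n + j] = s / L[j * n + j];
      }
    }
  return true;
}

// Haario-style adaptive multivariate proposal over the sampled coordinates;
// moments accumulate and the Cholesky refreshes during burn-in only
struct AMProposal {
  int n = 18;
  std::vector<int> idx;
  std::vector<double> sx, sxx, L;
  long count = 0;
  bool ready = false;
  double lambda = 0.5;            // global scale on the Haario proposal
  double win_acc = 0, win_try = 0;

  void adapt_scale() {
    // steer joint acceptance toward ~0.2 during burn-in
    if (win_try >= 50) {
      double r = win_acc / win_try;
      lambda *= (r > 0.2) ? 1.3 : 0.7;
      lambda = std::min(std::max(lambda, 1e-3), 3.0);
      win_acc = win_try = 0;
    }
  }

  void init(const LogicalVector &update) {
    idx.clear();
    for (int j = 0; j < 18; ++j) if (update[j]) idx.push_back(j);
    n = (int)idx.size();
    sx.assign(n, 0.0);
    sxx.assign(n * n, 0.0);
  }
  void accumulate(const NumericVector &theta) {
    ++count;
    for (int a = 0; a < n; ++a) {
      double xa = theta[idx[a]];
      sx[a] += xa;
      for (int b = 0; b <= a; ++b) sxx[a * n + b] += xa * theta[idx[b]];
    }
  }
  void refresh() {
    if (count < 200) return;
    std::vector<double> A(n * n, 0.0);
    double sc = 2.38 * 2.38 / n;
    for (int a = 0; a < n; ++a)
      for (int b = 0; b <= a; ++b) {
        double cab = sxx[a * n + b] / count -
                     (sx[a] / count) * (sx[b] / count);
        A[a * n + b] = A[b * n + a] = sc * cab;
      }
    for (int a = 0; a < n; ++a) A[a * n + a] += 1e-8;
    ready = chol_lower(A, n, L);
  }
};

// Marginalized MH move on the 10 survival/recruitment coefficients:
// proposal from an adaptive sub-covariance, acceptance computed with the
// survivor/recruit allocation summed out of the likelihood (the
// observation and initial-abundance terms do not involve these
// coefficients), and the allocation redrawn from its conditional on
// acceptance. This is the move that carries the growth-preserving
// (omega, gamma) trade-off ridge, which per-cell updates cannot cross.
static void update_omgam_collapsed(DMMState &st, AMProposal &am, double *acc,
                                   double *tries) {
  if (!am.ready) return;
  int n = am.n;
  std::vector<double> z(n);
  for (int a = 0; a < n; ++a) z[a] = norm_rand();
  NumericVector prop = clone(st.theta);
  for (int a = 0; a < n; ++a) {
    double step = 0;
    for (int b = 0; b <= a; ++b) step += am.L[a * n + b] * z[b];
    prop[am.idx[a]] += am.lambda * step;
  }
  tries[0] += 1;
  am.win_try += 1;
  double d = st.ll_demog_marginal(&prop[5], &prop[10]) -
             st.ll_demog_marginal(&st.theta[5], &st.theta[10]);
  for (int a = 0; a < n; ++a) {
    int j = am.idx[a];
    d += R::dnorm(prop[j], 0.0, st.prior_sd, 1) -
         R::dnorm(st.theta[j], 0.0, st.prior_sd, 1);
  }
  if (d >= 0 || unif_rand() < std::exp(d)) {
    st.theta = prop;
    st.recompute_om(); st.recompute_ga();
    st.redraw_alloc();
    acc[0] += 1;
    am.win_acc += 1;
  }
}

static void update_theta_joint(DMMState &st, AMProposal &am, double ll_cur_hint,
                               double *acc, double *tries) {
  if (!am.ready) return;
  int n = am.n;
  std::vector<double> z(n);
  for (int a = 0; a < n; ++a) z[a] = norm_rand();
  NumericVector prop = clone(st.theta);
  for (int a = 0; a < n; ++a) {
    double step = 0;
    for (int b = 0; b <= a; ++b) step += am.L[a * n + b] * z[b];
    prop[am.idx[a]] += am.lambda * step;
  }
  tries[0] += 1;
  am.win_try += 1;
  double lp_prop = st.log_prior(prop);
  if (lp_prop == NEG_INF) return;
  double ll_cur = ll_cur_hint;
  double ll_prop = st.ll_init(&prop[0]) + st.ll_surv(&prop[5]) +
                   st.ll_rec(&prop[10]) + st.ll_obs(&prop[15]);
  double d = ll_prop + lp_prop - ll_cur - st.log_prior(st.theta);
  if (d >= 0 || unif_rand() < std::exp(d)) {
    st.theta = prop;
    st.recompute_lam(); st.recompute_om(); st.recompute_ga(); st.recompute_p();
    acc[0] += 1;
    am.win_acc += 1;
  }
}

// [[Rcpp::export]]
List dmm_mcmc_chain(IntegerMatrix X, NumericVector Z, NumericMatrix effort,
                    NumericMatrix effort_sd, NumericMatrix temp,
                    NumericVector theta_init, LogicalVector update_mask,
                    IntegerMatrix N_init, double prior_sd, int n_iter,
                    int n_burn, int thin, IntegerVector latent_jump,
                    int latent_sweeps, int joint_reps) {
  DMMState st;
  st.I = X.nrow(); st.T = X.ncol();
  st.X = X; st.Z = Z;
  st.effort = clone(effort);
  st.effort_hat = effort;
  st.sdE = effort_sd; st.temp = temp;
  st.theta = clone(theta_init);
  st.update = update_mask;
  st.prior_sd = prior_sd;
  st.N = clone(N_init);
  st.S = IntegerMatrix(st.I, st.T);
  st.R = IntegerMatrix(st.I, st.T);
  for (int i = 0; i < st.I; ++i)
    for (int t = 1; t < st.T; ++t) {
      st.S(i, t) = std::min(st.N(i, t), st.N(i, t - 1));
      st.R(i, t) = st.N(i, t) - st.S(i, t);
    }
  st.lam.assign(st.I, 0.0); st.llam.assign(st.I, 0.0);
  st.om = NumericMatrix(st.I, st.T); st.lom = NumericMatrix(st.I, st.T);
  st.l1mom = NumericMatrix(st.I, st.T);
  st.ga = NumericMatrix(st.I, st.T); st.lga = NumericMatrix(st.I, st.T);
  st.p = NumericMatrix(st.I, st.T); st.lpr = NumericMatrix(st.I, st.T);
  st.l1mpr = NumericMatrix(st.I, st.T);
  st.recompute_lam(); st.recompute_om(); st.recompute_ga(); st.recompute_p();

  std::vector<double> scales(18, 0.1), acc_theta(18, 0.0), try_theta(18, 0.0);
  std::vector<double> acc_win(18, 0.0), try_win(18, 0.0);
  double acc_lat[3] = {0, 0, 0}, try_lat[3] = {0, 0, 0};
  double acc_eff[1] = {0}, try_eff[1] = {0};
  double acc_joint[1] = {0}, try_joint[1] = {0};
  double acc_og[1] = {0}, try_og[1] = {0};
  AMProposal am; am.init(update_mask);
  LogicalVector og_mask(18);
  for (int j = 5; j < 15; ++j) og_mask[j] = update_mask[j];
  AMProposal amog; amog.init(og_mask);

  int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix theta_draws(n_keep, 18);
  NumericMatrix N_draws(n_keep, st.I * st.T);
  IntegerMatrix S_draws(n_keep, st.I * st.T), R_draws(n_keep, st.I * st.T);
  int kept = 0;
  bool any_update = false;
  for (int j = 0; j < 18; ++j) if (update_mask[j]) any_update = true;

  for (int it = 0; it < n_iter; ++it) {
    for (int sw = 0; sw < latent_sweeps; ++sw)
      update_latent(st, latent_jump, true, acc_lat, try_lat);
    // the marginalized shift is the costliest latent move; on large
    // panels every other iteration is enough
    if (st.I * st.T <= 1000 || it % 2 == 1)
      update_shift_marginal(st, latent_jump, &acc_lat[2], &try_lat[2]);
    if (any_update) {
      std::vector<double> a0(acc_theta), t0(try_theta);
      update_theta_univariate(st, scales, acc_theta, try_theta);
      for (int j = 0; j < 18; ++j) {
        acc_win[j] += acc_theta[j] - a0[j];
        try_win[j] += try_theta[j] - t0[j];
      }
      // classical adaptive Metropolis: the empirical covariance keeps
      // accumulating over the whole run (diminishing adaptation), which is
      // what eventually captures the long survival/recruitment ridges
      if (it >= n_burn / 8) { am.accumulate(st.theta); amog.accumulate(st.theta); }
      if (it >= n_burn / 2) {
        if (it % 200 == 0) {
          am.refresh(); amog.refresh();
          if (it < n_burn) { am.adapt_scale(); amog.adapt_scale(); }
        }
        for (int rep = 0; rep < joint_reps && am.ready; ++rep) {
          double ll_cur = st.ll_all();
          update_theta_joint(st, am, ll_cur, acc_joint, try_joint);
        }
        if (amog.n > 0 && it % 2 == 0)
          update_omgam_collapsed(st, amog, acc_og, try_og);
      }
    }
    update_effort(st, 1.0, acc_eff, try_eff);

    if (it < n_burn && (it + 1) % 50 == 0) {
      for (int j = 0; j < 18; ++j) {
        if (try_win[j] > 0) {
          double r = acc_win[j] / try_win[j];
          scales[j] *= (r > 0.44) ? 1.15 : 0.87;
          scales[j] = std::min(std::max(scales[j], 1e-4), 10.0);
        }
        acc_win[j] = try_win[j] = 0;
      }
    }

    if (it >= n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < 18; ++j) theta_draws(kept, j) = st.theta[j];
      for (int i = 0; i < st.I; ++i)
        for (int t = 0; t < st.T; ++t) {
          N_draws(kept, i + st.I * t) = st.N(i, t);
          S_draws(kept, i + st.I * t) = st.S(i, t);
          R_draws(kept, i + st.I * t) = st.R(i, t);
        }
      ++kept;
    }
  }

  NumericVector acc_rates = NumericVector::create(
      _["latent_init"] = try_lat[0] > 0 ? acc_lat[0] / try_lat[0] : NA_REAL,
      _["latent_sr"] = try_lat[1] > 0 ? acc_lat[1] / try_lat[1] : NA_REAL,
      _["latent_shift"] = try_lat[2] > 0 ? acc_lat[2] / try_lat[2] : NA_REAL,
      _["effort"] = try_eff[0] > 0 ? acc_eff[0] / try_eff[0] : NA_REAL,
      _["joint"] = try_joint[0] > 0 ? acc_joint[0] / try_joint[0] : NA_REAL,
      _["omgam_marginal"] = try_og[0] > 0 ? acc_og[0] / try_og[0] : NA_REAL);
  NumericVector acc_coef(18);
  for (int j = 0; j < 18; ++j)
    acc_coef[j] = try_theta[j] > 0 ? acc_theta[j] / try_theta[j] : NA_REAL;

  return List::create(_["theta"] = theta_draws, _["N"] = N_draws,
                      _["S"] = S_draws, _["R"] = R_draws,
                      _["accept"] = acc_rates, _["accept_coef"] = acc_coef,
                      _["n_kept"] = kept);
}
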