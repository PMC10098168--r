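// Metropolis-within-Gibbs sampler for node ages, branch rates, the global
// rate mu and the rate-model hyperparameters, under a truncated-normal root
// prior, a normalized uniform order-compatible prior on internal ages, hard
// calibration bounds, and a per-branch Poisson substitution-count
// likelihood. Models: 0 = UGAM (independent gamma branch multipliers),
// 1 = LN (autocorrelated lognormal node rates), 2 = CIR (mean-reverting
// square-root node rates). Uses R's RNG so set.seed() governs the chain.
#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Sampler {
  int ntip, ntot, root, model;
  std::vector<int> parent;                 // -1 for root
  std::vector<std::vector<int>> children;  // node -> child nodes
  std::vector<double> kby, lgam_k;         // counts by child node
  double L;
  std::vector<double> calmin, calmax;
  double pr_mean, pr_sd;
  bool use_lik, sample_hyper;
  double mu_pr_mean, hy_mean1, hy_mean2;
  int m;                                   // #internal nodes - 1

  std::vector<double> ages, nr, rb;        // state
  double mu, h1, h2;                       // hyper: nu | sigma2 | theta,sigma

  double lik_edge(int c) const {
    if (!use_lik) return 0.0;
    double dt = ages[parent[c]] - ages[c];
    double rbar = (model == 0) ? rb[c] : 0.5 * (nr[parent[c]] + nr[c]);
    double lam = rbar * mu * dt * L;
    double k = kby[c];
    if (lam <= 0.0) return (k > 0.0) ? NEG_INF : 0.0;
    return k * std::log(lam) - lam - lgam_k[c];
  }

  double rate_edge(int c) const {          // prior/transition term of branch c
    if (model == 0) {
      return R::dgamma(rb[c], 1.0 / h1, h1, 1);
    }
    double dt = ages[parent[c]] - ages[c];
    if (dt <= 0.0) return NEG_INF;
    double rp = nr[parent[c]], rc = nr[c];
    if (rp <= 0.0 || rc <= 0.0) return NEG_INF;
    if (model == 1) {                      // lognormal with martingale drift
      double s = std::sqrt(h1 * dt);
      if (!(s > 0.0)) return NEG_INF;
      return R::dnorm(std::log(rc), std::log(rp) - 0.5 * h1 * dt, s, 1) -
             std::log(rc);
    }
    // CIR exact transition via scaled noncentral chi-square
    double theta = h1, sig2 = h2 * h2;
    double em = std::exp(-theta * dt);
    double c2 = 2.0 * theta / (sig2 * (1.0 - em));
    double df = 4.0 * theta / sig2;
    double ncp = 2.0 * c2 * rp * em;
    return R::dnchisq(2.0 * c2 * rc, df, ncp, 1) + std::log(2.0 * c2);
  }

  double root_lp() const {
    double a = ages[root];
    if (a <= 0.0) return NEG_INF;
    return R::dnorm(a, pr_mean, pr_sd, 1) - m * std::log(a);
  }
  double mu_lp() const { return -mu / mu_pr_mean; }
  double hyper_lp() const {
    double lp = -h1 / hy_mean1;
    if (model == 2) {
      lp += -h2 / hy_mean2;
      if (2.0 * h1 <= h2 * h2) return NEG_INF;  // Feller condition
    }
    return lp;
  }

  double full_logpost() const {
    double lp = root_lp() + mu_lp() + hyper_lp();
    for (int c = 0; c < ntot; ++c) {
      if (c == root) continue;
      lp += lik_edge(c) + rate_edge(c);
    }
    return lp;
  }
};

static inline double reflect(double y, double lo, double hi) {
  double span = hi - lo;
  if (span <= 0.0) return lo;
  for (int it = 0; it < 100; ++it) {
    if (y < lo) y = 2.0 * lo - y;
    else if (y > hi) y = 2.0 * hi - y;
    else return y;
  }
  return lo + 0.5 * span;                  // pathological step size
}

// [[Rcpp::export]]
List mcmc_counts(IntegerMatrix edge0, int ntip, int root0,
                 NumericVector k_edge, double L, int model,
                 IntegerVector cal_node0, NumericVector cal_min,
                 NumericVector cal_max, double prior_mean, double prior_sd,
                 bool use_lik, bool sample_hyper,
                 int n_iter, int burnin, int thin,
                 NumericVector ages_init, double mu_init,
                 NumericVector hyper_init,
                 double mu_prior_mean, NumericVector hyper_prior_mean) {
  Sampler S;
  int nedge = edge0.nrow();
  S.ntip = ntip;
  S.ntot = ntip + (nedge - ntip) + 1;      // binary-or-not: tips + internals
  S.ntot = 0;
  for (int e = 0; e < nedge; ++e)
    S.ntot = std::max(S.ntot, std::max(edge0(e, 0), edge0(e, 1)) + 1);
  S.root = root0;
  S.model = model;
  S.L = L;
  S.use_lik = use_lik;
  S.sample_hyper = sample_hyper;
  S.pr_mean = prior_mean;
  S.pr_sd = prior_sd;
  S.mu_pr_mean = mu_prior_mean;
  S.hy_mean1 = hyper_prior_mean[0];
  S.hy_mean2 = (hyper_prior_mean.size() > 1) ? hyper_prior_mean[1] : 1.0;

  S.parent.assign(S.ntot, -1);
  S.children.assign(S.ntot, {});
  S.kby.assign(S.ntot, 0.0);
  S.lgam_k.assign(S.ntot, 0.0);
  for (int e = 0; e < nedge; ++e) {
    int p = edge0(e, 0), c = edge0(e, 1);
    S.parent[c] = p;
    S.children[p].push_back(c);
    S.kby[c] = k_edge[e];
    S.lgam_k[c] = std::lgamma(k_edge[e] + 1.0);
  }
  S.calmin.assign(S.ntot, 0.0);
  S.calmax.assign(S.ntot, R_PosInf);
  for (int i = 0; i < cal_node0.size(); ++i) {
    S.calmin[cal_node0[i]] = cal_min[i];
    S.calmax[cal_node0[i]] = cal_max[i];
  }

  std::vector<int> internals;
  for (int v = ntip; v < S.ntot; ++v) internals.push_back(v);
  S.m = (int)internals.size() - 1;

  // subtree bookkeeping for subtree-scale moves: for each internal
  // non-root node with at least one internal child, the internal nodes it
  // scales and the edges (children) whose lengths change
  std::vector<std::vector<int>> sub_nodes(S.ntot), sub_edges(S.ntot);
  std::vector<int> sub_candidates;
  for (int v : internals) {
    if (v == S.root) continue;
    bool has_internal_child = false;
    for (int c : S.children[v]) if (c >= ntip) has_internal_child = true;
    if (!has_internal_child) continue;
    std::vector<int> stack = {v};
    while (!stack.empty()) {
      int x = stack.back(); stack.pop_back();
      if (x >= ntip) sub_nodes[v].push_back(x);
      sub_edges[v].push_back(x);           // edge above x changes
      for (int c : S.children[x]) stack.push_back(c);
    }
    sub_candidates.push_back(v);
  }

  S.ages.assign(ages_init.begin(), ages_init.end());
  S.nr.assign(S.ntot, 1.0);
  S.rb.assign(S.ntot, 1.0);
  S.mu = mu_init;
  S.h1 = hyper_init[0];
  S.h2 = (hyper_init.size() > 1) ? hyper_init[1] : 0.0;

  // step sizes + adaptation bookkeeping
  std::vector<double> w_age(S.ntot, 0.3);  // fraction of the local interval
  double w_root = prior_sd * 0.5;          // absolute (unbounded above)
  double w_scale = 0.1, w_rate = 0.5, w_mu = 0.5, w_h1 = 0.5, w_h2 = 0.5;
  double w_sub = 0.1;
  std::vector<double> acc_age(S.ntot, 0.0), att_age(S.ntot, 0.0);
  double acc_root = 0, att_root = 0, acc_sc = 0, att_sc = 0;
  double acc_sub = 0, att_sub = 0;
  double w_mur = 0.3, acc_mur = 0, att_mur = 0;
  double acc_r = 0, att_r = 0, acc_mu = 0, att_mu = 0;
  double acc_h1 = 0, att_h1 = 0, acc_h2 = 0, att_h2 = 0;

  int nh = (model == 2) ? 2 : 1;
  int nsamp = (n_iter - burnin) / thin;
  int ncol = (int)internals.size() + 1 + nh + 1;
  NumericMatrix samples(nsamp, ncol);
  int row = 0;

  RNGScope scope;
  auto runif_sym = [](double h) { return (unif_rand() * 2.0 - 1.0) * h; };

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- node ages ---------------------------------------------------
    for (int v : internals) {
      double lo = S.calmin[v], hi;
      for (int c : S.children[v]) lo = std::max(lo, S.ages[c]);
      bool is_root = (v == S.root);
      hi = is_root ? S.calmax[v]
                   : std::min(S.ages[S.parent[v]], S.calmax[v]);
      double x = S.ages[v], y;
      att_age[v] += 1;
      if (is_root && !std::isfinite(hi)) {
        y = x + runif_sym(w_root);
        att_root += 1;
        if (y <= lo) continue;
      } else {
        if (hi <= lo) continue;
        y = reflect(x + runif_sym(w_age[v] * (hi - lo)), lo, hi);
      }
      double old_lp = 0.0, new_lp = 0.0;
      if (is_root) old_lp += S.root_lp();
      if (!is_root) old_lp += S.lik_edge(v) + S.rate_edge(v);
      for (int c : S.children[v]) old_lp += S.lik_edge(c) + S.rate_edge(c);
      S.ages[v] = y;
      if (is_root) new_lp += S.root_lp();
      if (!is_root) new_lp += S.lik_edge(v) + S.rate_edge(v);
      for (int c : S.children[v]) new_lp += S.lik_edge(c) + S.rate_edge(c);
      if (std::log(unif_rand()) < new_lp - old_lp) {
        acc_age[v] += 1;
        if (is_root && !std::isfinite(S.calmax[v])) acc_root += 1;
      } else {
        S.ages[v] = x;
      }
    }

    // --- joint age/mu rescaling (time-rate confounding move) ---------
    {
      att_sc += 1;
      double lc = runif_sym(w_scale);
      double c = std::exp(lc);
      bool ok = true;
      for (int v : internals) {
        double a = S.ages[v] * c;
        if (a < S.calmin[v] || a > S.calmax[v]) { ok = false; break; }
      }
      if (ok) {
        double old_lp = S.root_lp() + S.mu_lp();
        if (model != 0)
          for (int b = 0; b < S.ntot; ++b)
            if (b != S.root) old_lp += S.rate_edge(b);
        std::vector<double> save(S.ages);
        double mu_save = S.mu;
        for (int v : internals) S.ages[v] *= c;
        S.mu /= c;
        double new_lp = S.root_lp() + S.mu_lp();
        if (model != 0)
          for (int b = 0; b < S.ntot; ++b)
            if (b != S.root) new_lp += S.rate_edge(b);
        // Jacobian: (m+1) ages scaled by c, mu by 1/c
        double delta = new_lp - old_lp + S.m * lc;
        if (std::log(unif_rand()) < delta) {
          acc_sc += 1;
        } else {
          S.ages = save;
          S.mu = mu_save;
        }
      }
    }

    // --- subtree scaling (decorrelates nested node ages) -------------
    for (int v : sub_candidates) {
      att_sub += 1;
      double lc = runif_sym(w_sub);
      double c = std::exp(lc);
      bool ok = S.ages[v] * c < S.ages[S.parent[v]];
      if (ok) {
        for (int x : sub_nodes[v]) {
          double a = S.ages[x] * c;
          if (a < S.calmin[x] || a > S.calmax[x]) { ok = false; break; }
        }
      }
      if (!ok) continue;
      double old_lp = 0.0, new_lp = 0.0;
      for (int x : sub_edges[v]) old_lp += S.lik_edge(x) + S.rate_edge(x);
      std::vector<double> save;
      save.reserve(sub_nodes[v].size());
      for (int x : sub_nodes[v]) {
        save.push_back(S.ages[x]);
        S.ages[x] *= c;
      }
      for (int x : sub_edges[v]) new_lp += S.lik_edge(x) + S.rate_edge(x);
      double delta = new_lp - old_lp + (double)sub_nodes[v].size() * lc;
      if (std::log(unif_rand()) < delta) {
        acc_sub += 1;
      } else {
        for (size_t i = 0; i < sub_nodes[v].size(); ++i)
          S.ages[sub_nodes[v][i]] = save[i];
      }
    }

    // --- rates -------------------------------------------------------
    if (model == 0) {
      for (int b = 0; b < S.ntot; ++b) {
        if (b == S.root) continue;
        att_r += 1;
        double lstep = runif_sym(w_rate);
        double x = S.rb[b], y = x * std::exp(lstep);
        double old_lp = S.lik_edge(b) + S.rate_edge(b);
        S.rb[b] = y;
        double new_lp = S.lik_edge(b) + S.rate_edge(b);
        if (std::log(unif_rand()) < new_lp - old_lp + lstep) acc_r += 1;
        else S.rb[b] = x;
      }
    } else {
      for (int v = 0; v < S.ntot; ++v) {
        if (v == S.root) continue;
        att_r += 1;
        double lstep = runif_sym(w_rate);
        double x = S.nr[v], y = x * std::exp(lstep);
        double old_lp = S.lik_edge(v) + S.rate_edge(v);
        for (int c : S.children[v]) old_lp += S.lik_edge(c) + S.rate_edge(c);
        S.nr[v] = y;
        double new_lp = S.lik_edge(v) + S.rate_edge(v);
        for (int c : S.children[v]) new_lp += S.lik_edge(c) + S.rate_edge(c);
        if (std::log(unif_rand()) < new_lp - old_lp + lstep) acc_r += 1;
        else S.nr[v] = x;
      }
    }

    // --- mu ----------------------------------------------------------
    {
      att_mu += 1;
      double lstep = runif_sym(w_mu);
      double x = S.mu, y = x * std::exp(lstep);
      double old_lp = S.mu_lp();
      if (use_lik)
        for (int b = 0; b < S.ntot; ++b)
          if (b != S.root) old_lp += S.lik_edge(b);
      S.mu = y;
      double new_lp = S.mu_lp();
      if (use_lik)
        for (int b = 0; b < S.ntot; ++b)
          if (b != S.root) new_lp += S.lik_edge(b);
      if (std::log(unif_rand()) < new_lp - old_lp + lstep) acc_mu += 1;
      else S.mu = x;
    }

    // --- mu vs multipliers rescale (UGAM ridge: only mu*r_b is
    //     likelihood-identified) -------------------------------------
    if (model == 0) {
      att_mur += 1;
      double lc = runif_sym(w_mur);
      double c = std::exp(lc);
      double old_lp = S.mu_lp();
      for (int b = 0; b < S.ntot; ++b)
        if (b != S.root) old_lp += S.rate_edge(b);
      double mu_save = S.mu;
      std::vector<double> rb_save(S.rb);
      S.mu *= c;
      int nb = 0;
      for (int b = 0; b < S.ntot; ++b)
        if (b != S.root) { S.rb[b] /= c; ++nb; }
      double new_lp = S.mu_lp();
      for (int b = 0; b < S.ntot; ++b)
        if (b != S.root) new_lp += S.rate_edge(b);
      double delta = new_lp - old_lp + (1.0 - nb) * lc;
      if (std::log(unif_rand()) < delta) {
        acc_mur += 1;
      } else {
        S.mu = mu_save;
        S.rb = rb_save;
      }
    }

    // --- hyperparameters --------------------------------------------
    if (sample_hyper) {
      att_h1 += 1;
      double lstep = runif_sym(w_h1);
      double x = S.h1, y = x * std::exp(lstep);
      double old_lp = S.hyper_lp();
      for (int b = 0; b < S.ntot; ++b)
        if (b != S.root) old_lp += S.rate_edge(b);
      S.h1 = y;
      double new_lp = S.hyper_lp();
      if (std::isfinite(new_lp))
        for (int b = 0; b < S.ntot; ++b)
          if (b != S.root) new_lp += S.rate_edge(b);
      if (std::log(unif_rand()) < new_lp - old_lp + lstep) acc_h1 += 1;
      else S.h1 = x;

      if (model == 2) {
        att_h2 += 1;
        lstep = runif_sym(w_h2);
        x = S.h2; y = x * std::exp(lstep);
        old_lp = S.hyper_lp();
        for (int b = 0; b < S.ntot; ++b)
          if (b != S.root) old_lp += S.rate_edge(b);
        S.h2 = y;
        new_lp = S.hyper_lp();
        if (std::isfinite(new_lp))
          for (int b = 0; b < S.ntot; ++b)
            if (b != S.root) new_lp += S.rate_edge(b);
        if (std::log(unif_rand()) < new_lp - old_lp + lstep) acc_h2 += 1;
        else S.h2 = x;
      }
    }

    // --- adaptation during burn-in ----------------------------------
    if (iter <= burnin && iter % 50 == 0) {
      auto tune = [](double &w, double &acc, double &att,
                     double wmin, double wmax) {
        if (att < 1) return;
        double r = acc / att;
        if (r > 0.5) w = std::min(w * 1.25, wmax);
        else if (r < 0.2) w = std::max(w / 1.25, wmin);
        acc = att = 0;
      };
      for (int v : internals) {
        if (v == S.root && !std::isfinite(S.calmax[v])) continue;
        tune(w_age[v], acc_age[v], att_age[v], 0.01, 1.9);
      }
      tune(w_root, acc_root, att_root, S.pr_sd * 1e-3, S.pr_sd * 10);
      tune(w_scale, acc_sc, att_sc, 1e-3, 2.0);
      tune(w_sub, acc_sub, att_sub, 1e-3, 2.0);
      tune(w_mur, acc_mur, att_mur, 1e-3, 5.0);
      tune(w_rate, acc_r, att_r, 1e-3, 5.0);
      tune(w_mu, acc_mu, att_mu, 1e-3, 5.0);
      tune(w_h1, acc_h1, att_h1, 1e-3, 5.0);
      if (model == 2) tune(w_h2, acc_h2, att_h2, 1e-3, 5.0);
    }

    // --- storage -----------------------------------------------------
    if (iter > burnin && (iter - burnin) % thin == 0 && row < nsamp) {
      int j = 0;
      for (int v : internals) samples(row, j++) = S.ages[v];
      samples(row, j++) = S.mu;
      samples(row, j++) = S.h1;
      if (nh == 2) samples(row, j++) = S.h2;
      samples(row, j) = S.full_logpost();
      ++row;
    }
  }

  double n_post = std::max(1.0, (double)(n_iter - burnin));
  NumericVector acc = NumericVector::create(
      _["rates"] = att_r > 0 ? acc_r / att_r : NA_REAL,
      _["mu"] = att_mu > 0 ? acc_mu / att_mu : NA_REAL,
      _["scale"] = att_sc > 0 ? acc_sc / att_sc : NA_REAL);
  (void)n_post;
  return List::create(_["samples"] = samples, _["acceptance"] = acc);
}
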