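// No-U-Turn sampler for the hierarchical logistic volume models.
//
// Non-centered parameterization: beta[r,g] = exp(t[k(r),g]) * z[r,g] with
// z ~ N(0,1), sigma_k = exp(t_k) ~ half-normal(1) (sampled on the log scale,
// Jacobian included), alpha ~ N(0,1).  scale_idx maps region -> scale
// component: one shared scale per network (network-level model) or one scale
// per region (region-level model).  group duplicates the beta block, e.g. for
// the sex-stratified variant.
//
// All randomness goes through R's RNG so set.seed() governs the chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct HierLogistic {
  mat X;               // n x p
  vec y;               // 0/1
  uvec sex;            // 1 = man, 0 = woman
  vec age;             // z-scored
  uvec scale_idx;      // p, 0-based -> K
  uvec group;          // n, 0-based -> G
  int n, p, K, G, P;
  std::vector<uvec> rows_g;   // row indices per group
  std::vector<mat> Xg;        // cached row blocks
  uvec men_idx, women_idx;

  void init() {
    n = X.n_rows; p = X.n_cols;
    K = scale_idx.max() + 1;
    G = group.max() + 1;
    P = p * G + K * G + 4;
    rows_g.resize(G); Xg.resize(G);
    for (int g = 0; g < G; ++g) {
      rows_g[g] = find(group == (unsigned)g);
      Xg[g] = X.rows(rows_g[g]);
    }
    men_idx = find(sex == 1u);
    women_idx = find(sex == 0u);
  }

  // theta = [z (p*G), t (K*G), alpha(4)]
  double logp_grad(const vec& th, vec& grad) const {
    const double* zp = th.memptr();
    const double* tp = th.memptr() + p * G;
    const double* ap = th.memptr() + p * G + K * G;

    mat beta(p, G), sig(p, G);
    for (int g = 0; g < G; ++g)
      for (int r = 0; r < p; ++r) {
        double s = std::exp(tp[scale_idx[r] + g * K]);
        sig(r, g) = s;
        beta(r, g) = s * zp[r + g * p];
      }

    vec eta(n);
    for (int g = 0; g < G; ++g)
      eta(rows_g[g]) = Xg[g] * beta.col(g);
    for (int i = 0; i < n; ++i)
      eta[i] += sex[i] ? (ap[0] + ap[2] * age[i]) : (ap[1] + ap[3] * age[i]);

    // log-likelihood: sum y*eta - log1p(exp(eta)), stable
    double ll = 0.0;
    vec resid(n);
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      if (e > 0) {
        double u = std::exp(-e);                  // in (0,1]
        ll += y[i] * e - (e + std::log1p(u));
        resid[i] = y[i] - 1.0 / (1.0 + u);
      } else {
        double u = std::exp(e);
        ll += y[i] * e - std::log1p(u);
        resid[i] = y[i] - u / (1.0 + u);
      }
    }

    // priors (+ Jacobian for t): z,alpha ~ N(0,1); sigma ~ HN(1)
    double lp = ll;
    for (int i = 0; i < p * G; ++i) lp -= 0.5 * zp[i] * zp[i];
    for (int i = 0; i < K * G; ++i) {
      double e2t = std::exp(2.0 * tp[i]);
      lp += -0.5 * e2t + tp[i];
    }
    for (int i = 0; i < 4; ++i) lp -= 0.5 * ap[i] * ap[i];

    grad.set_size(P);
    double* gz = grad.memptr();
    double* gt = grad.memptr() + p * G;
    double* ga = grad.memptr() + p * G + K * G;
    for (int i = 0; i < K * G; ++i) gt[i] = 1.0 - std::exp(2.0 * tp[i]);

    for (int g = 0; g < G; ++g) {
      vec gbeta = Xg[g].t() * resid(rows_g[g]);
      for (int r = 0; r < p; ++r) {
        gz[r + g * p] = gbeta[r] * sig(r, g) - zp[r + g * p];
        gt[scale_idx[r] + g * K] += gbeta[r] * beta(r, g);
      }
    }
    vec ra = resid % age;
    ga[0] = accu(resid(men_idx)) - ap[0];
    ga[1] = accu(resid(women_idx)) - ap[1];
    ga[2] = accu(ra(men_idx)) - ap[2];
    ga[3] = accu(ra(women_idx)) - ap[3];
    return lp;
  }
};

struct Hamiltonian {
  const HierLogistic* m;
  vec invmass;  // = estimated posterior variances (diagonal metric)

  double kinetic(const vec& r) const { return 0.5 * dot(r % invmass, r); }

  vec draw_momentum(int P) const {
    vec r(P);
    for (int i = 0; i < P; ++i) r[i] = R::norm_rand() / std::sqrt(invmass[i]);
    return r;
  }

  // one leapfrog step; returns new logp, updates grad
  double leapfrog(vec& q, vec& r, double eps, vec& grad) const {
    r += 0.5 * eps * grad;
    q += eps * (invmass % r);
    double lp = m->logp_grad(q, grad);
    r += 0.5 * eps * grad;
    return lp;
  }
};

struct Tree {
  vec qm, rm, gm, qp, rp, gp;   // minus / plus states with gradients
  vec qprop;
  double lpprop;
  double n;        // slice-acceptable states (Hoffman & Gelman alg. 6)
  bool s;          // no U-turn, no divergence
  double alpha;    // sum of accept probs (for dual averaging)
  int nalpha;
  bool diverged;
};

class Nuts {
public:
  const HierLogistic* model;
  Hamiltonian ham;
  double logu, H0;
  int maxdepth;
  bool any_divergence;

  bool uturn(const vec& qp, const vec& qm, const vec& rp, const vec& rm) const {
    vec dq = qp - qm;
    return dot(dq, ham.invmass % rp) < 0 || dot(dq, ham.invmass % rm) < 0;
  }

  Tree base_case(const vec& q, const vec& r, const vec& g, int v, double eps) {
    Tree t;
    t.qm = q; t.rm = r; t.gm = g;
    double lp = ham.leapfrog(t.qm, t.rm, v * eps, t.gm);
    double H = lp - ham.kinetic(t.rm);
    t.qp = t.qm; t.rp = t.rm; t.gp = t.gm;
    t.qprop = t.qm; t.lpprop = lp;
    t.n = (logu <= H) ? 1.0 : 0.0;
    t.diverged = (logu > H + 1000.0);
    t.s = !t.diverged;
    double a = H - H0;
    t.alpha = (a > 0) ? 1.0 : std::exp(a);
    if (!std::isfinite(H)) { t.alpha = 0.0; t.diverged = true; t.s = false; }
    t.nalpha = 1;
    return t;
  }

  Tree build(const vec& q, const vec& r, const vec& g, int v, int j, double eps) {
    if (j == 0) return base_case(q, r, g, v, eps);
    Tree t1 = build(q, r, g, v, j - 1, eps);
    if (!t1.s) return t1;
    Tree t2 = (v == -1) ? build(t1.qm, t1.rm, t1.gm, v, j - 1, eps)
                        : build(t1.qp, t1.rp, t1.gp, v, j - 1, eps);
    if (v == -1) { t1.qm = t2.qm; t1.rm = t2.rm; t1.gm = t2.gm; }
    else         { t1.qp = t2.qp; t1.rp = t2.rp; t1.gp = t2.gp; }
    double ntot = t1.n + t2.n;
    if (ntot > 0 && R::unif_rand() < t2.n / ntot) {
      t1.qprop = t2.qprop; t1.lpprop = t2.lpprop;
    }
    t1.n = ntot;
    t1.alpha += t2.alpha; t1.nalpha += t2.nalpha;
    t1.diverged = t1.diverged || t2.diverged;
    t1.s = t2.s && !uturn(t1.qp, t1.qm, t1.rp, t1.rm);
    return t1;
  }

  // one NUTS transition; returns mean accept stat, updates q/lp/grad
  double transition(vec& q, double& lp, vec& grad, double eps, int& depth_out) {
    vec r0 = ham.draw_momentum(q.n_elem);
    H0 = lp - ham.kinetic(r0);
    logu = H0 - R::exp_rand();   // log of u ~ U(0, exp(H0))
    vec qm = q, qp = q, rm = r0, rp = r0, gm = grad, gp = grad;
    double n = 1.0, alpha_sum = 0.0;
    int nalpha = 0;
    bool s = true;
    int j = 0;
    any_divergence = false;
    while (s && j < maxdepth) {
      int v = (R::unif_rand() < 0.5) ? -1 : 1;
      Tree t = (v == -1) ? build(qm, rm, gm, v, j, eps)
                         : build(qp, rp, gp, v, j, eps);
      if (v == -1) { qm = t.qm; rm = t.rm; gm = t.gm; }
      else         { qp = t.qp; rp = t.rp; gp = t.gp; }
      if (t.s && R::unif_rand() < t.n / n) {
        q = t.qprop; lp = t.lpprop;
      }
      n += t.n;
      alpha_sum += t.alpha; nalpha += t.nalpha;
      any_divergence = any_divergence || t.diverged;
      s = t.s && !uturn(qp, qm, rp, rm);
      ++j;
    }
    depth_out = j;
    model->logp_grad(q, grad);  // refresh gradient at accepted state
    return nalpha > 0 ? alpha_sum / nalpha : 0.0;
  }
};

double find_epsilon(const HierLogistic& m, const Hamiltonian& ham, vec q) {
  double eps = 0.1;
  vec grad;
  double lp = m.logp_grad(q, grad);
  vec r = ham.draw_momentum(q.n_elem);
  double H0 = lp - ham.kinetic(r);
  vec q1 = q, r1 = r, g1 = grad;
  double lp1 = ham.leapfrog(q1, r1, eps, g1);
  double H1 = lp1 - ham.kinetic(r1);
  if (!std::isfinite(H1)) H1 = H0 - 1e6;
  double a = (H1 - H0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= (a > 0) ? 2.0 : 0.5;
    q1 = q; r1 = ham.draw_momentum(q.n_elem);
    H0 = lp - ham.kinetic(r1);
    g1 = grad;
    lp1 = ham.leapfrog(q1, r1, eps, g1);
    H1 = lp1 - ham.kinetic(r1);
    if (!std::isfinite(H1)) H1 = H0 - 1e6;
    if (a * (H1 - H0) < a * std::log(0.5)) break;
  }
  return eps;
}

} // namespace

// [[Rcpp::export(name = ".hier_logistic_logp_grad")]]
Rcpp::List hier_logistic_logp_grad(const arma::mat& X, const arma::vec& y,
                                   const arma::uvec& sex, const arma::vec& age,
                                   const arma::uvec& scale_idx,
                                   const arma::uvec& group,
                                   const arma::vec& theta) {
  HierLogistic m{X, y, sex, age, scale_idx, group};
  m.init();
  vec grad;
  double lp = m.logp_grad(theta, grad);
  return Rcpp::List::create(Rcpp::Named("logp") = lp,
                            Rcpp::Named("grad") = grad);
}

// One chain. warmup iterations are discarded; returns draws of the
// *transformed* parameters (beta, sigma, alpha) plus sampler diagnostics.
// [[Rcpp::export(name = ".nuts_chain")]]
Rcpp::List nuts_chain(const arma::mat& X, const arma::vec& y,
                      const arma::uvec& sex, const arma::vec& age,
                      const arma::uvec& scale_idx, const arma::uvec& group,
                      int warmup, int iter, double target_accept,
                      int max_treedepth, double init_jitter) {
  HierLogistic m{X, y, sex, age, scale_idx, group};
  m.init();
  const int P = m.P, pG = m.p * m.G, KG = m.K * m.G;

  Rcpp::RNGScope rngscope;

  vec q(P);
  for (int i = 0; i < P; ++i) q[i] = (R::unif_rand() * 2.0 - 1.0) * init_jitter;
  // start log-scales low so initial betas are modest
  for (int i = pG; i < pG + KG; ++i) q[i] -= 2.0;

  Nuts nuts;
  nuts.model = &m;
  nuts.ham.m = &m;
  nuts.ham.invmass = vec(P, fill::ones);
  nuts.maxdepth = max_treedepth;

  vec grad;
  double lp = m.logp_grad(q, grad);

  // dual averaging (Hoffman & Gelman)
  double eps = find_epsilon(m, nuts.ham, q);
  double mu = std::log(10.0 * eps), logepsbar = 0.0, Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int adapt_count = 0;

  // metric window [w_lo, w_hi) of warmup
  int w_lo = (int)(0.25 * warmup), w_hi = (int)(0.75 * warmup);
  running_stat_vec<vec> acc;

  int total = warmup + iter;
  mat draws(iter, pG + KG + 4);
  int divergences = 0, max_depth_hits = 0;
  double accept_sum = 0.0;

  for (int it = 0; it < total; ++it) {
    int depth = 0;
    double astat = nuts.transition(q, lp, grad, eps, depth);
    bool warm = it < warmup;

    if (warm) {
      ++adapt_count;
      Hbar = (1.0 - 1.0 / (adapt_count + t0)) * Hbar +
             (target_accept - astat) / (adapt_count + t0);
      double logeps = mu - std::sqrt((double)adapt_count) / gamma * Hbar;
      double w = std::pow((double)adapt_count, -kappa);
      logepsbar = w * logeps + (1.0 - w) * logepsbar;
      eps = std::exp(logeps);

      if (it >= w_lo && it < w_hi) acc(q);
      if (it == w_hi - 1 && acc.count() > 10) {
        vec v = acc.var();
        double nsamp = acc.count();
        nuts.ham.invmass = (nsamp / (nsamp + 5.0)) * v +
                           (5.0 / (nsamp + 5.0)) * 1e-3 * vec(P, fill::ones);
        eps = find_epsilon(m, nuts.ham, q);
        mu = std::log(10.0 * eps);
        Hbar = 0.0; logepsbar = 0.0; adapt_count = 0;
      }
    } else {
      if (it == warmup) eps = std::exp(logepsbar);
      if (nuts.any_divergence) ++divergences;
      if (depth >= max_treedepth) ++max_depth_hits;
      accept_sum += astat;
      int row = it - warmup;
      // transform: beta, sigma, alpha
      for (int g = 0; g < m.G; ++g)
        for (int r = 0; r < m.p; ++r) {
          double s = std::exp(q[pG + scale_idx[r] + g * m.K]);
          draws(row, r + g * m.p) = s * q[r + g * m.p];
        }
      for (int i = 0; i < KG; ++i) draws(row, pG + i) = std::exp(q[pG + i]);
      for (int i = 0; i < 4; ++i) draws(row, pG + KG + i) = q[pG + KG + i];
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("divergences") = divergences,
      Rcpp::Named("max_depth_hits") = max_depth_hits,
      Rcpp::Named("mean_accept") = accept_sum / iter,
      Rcpp::Named("step_size") = eps);
}
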