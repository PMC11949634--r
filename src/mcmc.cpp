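// Adaptive blockwise random-walk Metropolis sampler for Bernoulli and
// cumulative-logit (ordinal) mixed models with optional monotonic ordinal
// predictors. Blocks: fixed effects (joint MVN proposal, Haario-style
// covariance adaptation), monotonic simplexes (additive-logistic scale),
// random intercepts (scalar updates, per-factor adaptive scale), RE standard
// deviations (log scale), ordinal cutpoints (first cutpoint + log increments).
// Adaptation runs during warmup only, so post-warmup draws form a valid
// fixed-kernel Markov chain.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TARGET_SCALAR = 0.44;
static const double TARGET_BLOCK  = 0.234;

static inline double log1p_exp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double plogis_(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// log-likelihood over a subset of rows given the full linear predictor
static double loglik_rows(const arma::vec& eta, const arma::ivec& y,
                          int family, const arma::vec& tau,
                          const arma::uvec& rows) {
  double ll = 0.0;
  const int K = tau.n_elem + 1;
  for (arma::uword r = 0; r < rows.n_elem; ++r) {
    arma::uword i = rows[r];
    if (family == 0) {
      ll += y[i] * eta[i] - log1p_exp(eta[i]);
    } else {
      int k = y[i]; // 1..K
      double upper = (k == K) ? 1.0 : plogis_(tau[k - 1] - eta[i]);
      double lower = (k == 1) ? 0.0 : plogis_(tau[k - 2] - eta[i]);
      double p = upper - lower;
      ll += std::log(p > 1e-300 ? p : 1e-300);
    }
  }
  return ll;
}

static double loglik_all(const arma::vec& eta, const arma::ivec& y,
                         int family, const arma::vec& tau) {
  arma::uvec rows = arma::regspace<arma::uvec>(0, y.n_elem - 1);
  return loglik_rows(eta, y, family, tau, rows);
}

// monotonic contribution column for one term: D * cumsum(zeta)[x], 0 at x=0
static arma::vec mo_column(const arma::ivec& x, const arma::vec& zeta) {
  int D = zeta.n_elem;
  arma::vec cs = arma::cumsum(zeta);
  arma::vec out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i)
    out[i] = (x[i] == 0) ? 0.0 : D * cs[x[i] - 1];
  return out;
}

// additive-logistic: gamma in R^{D-1} -> simplex of length D (last is baseline)
static arma::vec softmax_simplex(const arma::vec& gamma) {
  int D = gamma.n_elem + 1;
  arma::vec z(D);
  double mx = 0.0;
  for (int i = 0; i < D - 1; ++i) mx = std::max(mx, gamma[i]);
  double s = std::exp(0.0 - mx);
  z[D - 1] = s;
  for (int i = 0; i < D - 1; ++i) { z[i] = std::exp(gamma[i] - mx); s += z[i]; }
  return z / s;
}

// log prior density of gamma under Dirichlet(1,..,1) on the simplex,
// including the Jacobian of the additive-logistic transform (= prod zeta_i)
static double log_prior_gamma(const arma::vec& zeta) {
  return arma::accu(arma::log(zeta + 1e-300));
}

struct AdaptiveBlock {
  int d;
  double log_sc;
  arma::vec mean;
  arma::mat M2;     // Welford sum of squares
  arma::mat chol;   // proposal shape (upper triangular)
  long t;
  bool sample_shape = false;
  AdaptiveBlock(int dim, double init_sd) : d(dim), t(0) {
    log_sc = 2.0 * std::log(init_sd);
    mean = arma::zeros(d);
    M2 = arma::zeros(d, d);
    chol = arma::eye(d, d);
  }
  arma::vec propose(const arma::vec& cur) {
    arma::vec z(d);
    for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
    return cur + std::exp(0.5 * log_sc) * (chol.t() * z);
  }
  void adapt(const arma::vec& x, double acc_prob, long iter) {
    ++t;
    double g = std::pow((double)t + 10.0, -0.6);
    log_sc += g * (acc_prob - (d == 1 ? TARGET_SCALAR : TARGET_BLOCK));
    if (t == 1) { mean = x; return; }
    arma::vec delta = x - mean;
    mean += delta / (double)t;
    M2 += delta * (x - mean).t();
    // replace the proposal shape with the (symmetrized) sample covariance
    // once enough genuine samples have accumulated
    if (d > 1 && t > 4 * d && t % 25 == 0) {
      arma::mat C = 0.5 * (M2 + M2.t()) / (double)(t - 1)
        + 1e-10 * arma::eye(d, d);
      arma::mat L;
      if (arma::chol(L, C)) {
        chol = L;
        // on the first switch to the sample shape, restart the scale at
        // the canonical 2.38^2/d; afterwards the Robbins-Monro tuning owns it
        if (!sample_shape) { log_sc = std::log(2.38 * 2.38 / d); sample_shape = true; }
      }
    }
  }
};

// [[Rcpp::export]]
List mcmc_glmm_chain(int family, IntegerVector y_, arma::mat X,
                     List mo_x_, List mo_D_,
                     List re_index_, IntegerVector re_nlev,
                     int K, int iter, int warmup,
                     double beta_prior_sd, double tau_prior_sd,
                     List inits, int intercept_col,
                     IntegerVector shift_factor, IntegerVector shift_col,
                     List shift_xlev, arma::mat beta_prop_cov) {
  const int n = y_.size();
  arma::ivec y(n);
  arma::vec y_d(n);
  for (int i = 0; i < n; ++i) { y[i] = y_[i]; y_d[i] = y_[i]; }
  const int p = X.n_cols;
  const int M = mo_x_.size();
  const int F = re_index_.size();
  const int ncut = (family == 1) ? (K - 1) : 0;

  // monotonic data
  std::vector<arma::ivec> mo_x(M);
  std::vector<int> mo_D(M);
  for (int m = 0; m < M; ++m) {
    IntegerVector v = mo_x_[m];
    arma::ivec xv(n);
    for (int i = 0; i < n; ++i) xv[i] = v[i];
    mo_x[m] = xv;
    mo_D[m] = as<int>(mo_D_[m]);
  }

  // RE row indices per level
  std::vector<arma::ivec> re_idx(F);
  std::vector<std::vector<arma::uvec> > level_rows(F);
  for (int f = 0; f < F; ++f) {
    IntegerVector v = re_index_[f]; // 0-based level per row
    arma::ivec iv(n);
    for (int i = 0; i < n; ++i) iv[i] = v[i];
    re_idx[f] = iv;
    int L = re_nlev[f];
    std::vector<std::vector<arma::uword> > tmp(L);
    for (int i = 0; i < n; ++i) tmp[v[i]].push_back(i);
    level_rows[f].resize(L);
    for (int l = 0; l < L; ++l)
      level_rows[f][l] = arma::uvec(tmp[l]);
  }

  // state
  arma::vec beta = as<arma::vec>(inits["beta"]);       // length p
  arma::vec bmo  = (M > 0) ? as<arma::vec>(inits["bmo"]) : arma::vec();
  std::vector<arma::vec> gamma(M);
  std::vector<arma::vec> zeta(M);
  {
    List g0 = (M > 0) ? as<List>(inits["gamma"]) : List();
    for (int m = 0; m < M; ++m) {
      gamma[m] = as<arma::vec>(g0[m]);
      zeta[m] = softmax_simplex(gamma[m]);
    }
  }
  std::vector<arma::vec> u(F);
  arma::vec log_sd(F);
  {
    List u0 = (F > 0) ? as<List>(inits["u"]) : List();
    arma::vec s0 = (F > 0) ? as<arma::vec>(inits["log_sd"]) : arma::vec();
    for (int f = 0; f < F; ++f) u[f] = as<arma::vec>(u0[f]);
    log_sd = s0;
  }
  arma::vec tau;
  arma::vec dtau; // (tau1, log diff ...)
  if (family == 1) {
    tau = as<arma::vec>(inits["tau"]);
    dtau.set_size(ncut);
    dtau[0] = tau[0];
    for (int k = 1; k < ncut; ++k) dtau[k] = std::log(tau[k] - tau[k - 1]);
  }

  // cached linear predictor pieces
  arma::vec eta_fix = X * beta;
  arma::vec eta_mo = arma::zeros(n);
  std::vector<arma::vec> mo_cols(M);
  for (int m = 0; m < M; ++m) {
    mo_cols[m] = mo_column(mo_x[m], zeta[m]);
    eta_mo += bmo[m] * mo_cols[m];
  }
  arma::vec eta_re = arma::zeros(n);
  for (int f = 0; f < F; ++f)
    for (int i = 0; i < n; ++i) eta_re[i] += u[f][re_idx[f][i]];
  arma::vec eta = eta_fix + eta_mo + eta_re;

  double cur_ll = loglik_all(eta, y, family, tau);

  // adaptive blocks; the fixed-effect proposal starts from the Gaussian
  // curvature approximation so collinear designs mix from iteration one
  AdaptiveBlock blk_beta(p + M, 1.0);
  {
    arma::mat L;
    if (arma::chol(L, beta_prop_cov + 1e-10 * arma::eye(p + M, p + M))) {
      blk_beta.chol = L;
      blk_beta.log_sc = std::log(2.38 * 2.38 / (p + M));
    } else {
      blk_beta.log_sc = 2.0 * std::log(0.02);
    }
  }
  std::vector<AdaptiveBlock> blk_gamma;
  for (int m = 0; m < M; ++m) blk_gamma.push_back(AdaptiveBlock(mo_D[m] - 1, 0.1));
  arma::vec re_log_sc(F); re_log_sc.fill(2.0 * std::log(0.2));
  arma::vec sd_log_sc(F); sd_log_sc.fill(2.0 * std::log(0.3));
  arma::vec re_t(F, arma::fill::zeros), sd_t(F, arma::fill::zeros);
  arma::vec shift_log_sc(F); shift_log_sc.fill(2.0 * std::log(0.1));
  arma::vec shift_t(F, arma::fill::zeros);
  const int nsh = shift_factor.size();
  arma::vec al_log_sc(std::max(nsh, 1)); al_log_sc.fill(2.0 * std::log(0.1));
  arma::vec al_t(std::max(nsh, 1), arma::fill::zeros);
  // per shift pair: level means, within-level residual column, exactness
  std::vector<arma::vec> shift_xlev_v(nsh);
  std::vector<arma::vec> shift_resid(nsh);
  std::vector<bool> shift_exact(nsh);
  for (int s = 0; s < nsh; ++s) {
    shift_xlev_v[s] = as<arma::vec>(shift_xlev[s]);
    arma::vec resid = X.col(shift_col[s]);
    const arma::ivec& lev = re_idx[shift_factor[s]];
    for (int i = 0; i < n; ++i) resid[i] -= shift_xlev_v[s][lev[i]];
    shift_resid[s] = resid;
    shift_exact[s] = arma::abs(resid).max() < 1e-12;
  }
  AdaptiveBlock blk_tau(std::max(ncut, 1), 0.05);

  auto log_prior_beta = [&](const arma::vec& b, const arma::vec& bm) {
    double lp = 0.0;
    for (int j = 0; j < p; ++j) lp += R::dnorm(b[j], 0.0, beta_prior_sd, 1);
    for (int m = 0; m < M; ++m) lp += R::dnorm(bm[m], 0.0, beta_prior_sd, 1);
    return lp;
  };

  const int n_keep = iter - warmup;
  const int npar = p + M + [&]{ int s=0; for (int m=0;m<M;++m) s+=mo_D[m]; return s; }()
                 + [&]{ int s=0; for (int f=0;f<F;++f) s+=re_nlev[f]; return s; }()
                 + F + ncut;
  arma::mat draws(n_keep, npar);

  long accept_beta = 0, total_beta = 0;

  for (int it = 0; it < iter; ++it) {
    bool adapting = it < warmup;

    // ---- fixed-effect block ----
    // Bernoulli family: Gamerman-style update - propose from the one-step
    // IRLS Gaussian approximation of the conditional posterior given the
    // current random effects, with full Metropolis-Hastings correction.
    // Near-independence sampling of the whole block, immune to collinear
    // designs and large-n tightness.
    if (family == 0 && p + M > 0) {
      const int d = p + M;
      arma::mat Zc(n, d);
      if (p) Zc.cols(0, p - 1) = X;
      for (int m = 0; m < M; ++m) Zc.col(p + m) = mo_cols[m];
      arma::vec theta(d);
      if (p) theta.head(p) = beta;
      for (int m = 0; m < M; ++m) theta[p + m] = bmo[m];
      arma::mat P = arma::eye(d, d) / (beta_prior_sd * beta_prior_sd);

      // forward proposal built at the current state
      arma::vec pcur = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec W = arma::clamp(pcur % (1.0 - pcur), 1e-6, 0.25);
      arma::vec zres = Zc * theta + (y_d - pcur) / W;   // pseudo-data minus offset
      arma::mat A = Zc.t() * (Zc.each_col() % W) + P;
      arma::vec mth = arma::solve(A, Zc.t() * (W % zres), arma::solve_opts::likely_sympd);
      arma::mat Lf;
      bool ok = arma::chol(Lf, A);
      if (ok) {
        arma::vec xi(d);
        for (int k = 0; k < d; ++k) xi[k] = R::norm_rand();
        arma::vec theta_p = mth + arma::solve(arma::trimatu(Lf), xi);
        // forward density (up to the shared dimension constant)
        arma::vec dfwd = Lf * (theta_p - mth);
        double lq_fwd = arma::accu(arma::log(Lf.diag())) - 0.5 * arma::dot(dfwd, dfwd);
        // reverse proposal built at the proposed state
        arma::vec eta_p = Zc * theta_p + eta_re;
        arma::vec pprop = 1.0 / (1.0 + arma::exp(-eta_p));
        arma::vec Wp = arma::clamp(pprop % (1.0 - pprop), 1e-6, 0.25);
        arma::vec zres_p = Zc * theta_p + (y_d - pprop) / Wp;
        arma::mat Ap = Zc.t() * (Zc.each_col() % Wp) + P;
        arma::vec mth_p = arma::solve(Ap, Zc.t() * (Wp % zres_p), arma::solve_opts::likely_sympd);
        arma::mat Lr;
        if (arma::chol(Lr, Ap)) {
          arma::vec drev = Lr * (theta - mth_p);
          double lq_rev = arma::accu(arma::log(Lr.diag())) - 0.5 * arma::dot(drev, drev);
          double ll_p = loglik_all(eta_p, y, family, tau);
          double lp_cur = -0.5 * arma::dot(theta, theta) / (beta_prior_sd * beta_prior_sd);
          double lp_prop = -0.5 * arma::dot(theta_p, theta_p) / (beta_prior_sd * beta_prior_sd);
          double lr = (ll_p + lp_prop + lq_rev) - (cur_ll + lp_cur + lq_fwd);
          if (std::log(R::unif_rand()) < lr) {
            if (p) beta = theta_p.head(p);
            for (int m = 0; m < M; ++m) bmo[m] = theta_p[p + m];
            eta_fix = X * beta;
            eta_mo.zeros();
            for (int m = 0; m < M; ++m) eta_mo += bmo[m] * mo_cols[m];
            eta = eta_p; cur_ll = ll_p;
            ++accept_beta;
          }
          ++total_beta;
        }
      }
    }

    // adaptive random-walk fixed-effect block (ordinal family); several
    // updates per sweep to balance its effective sample size against the
    // cheap scalar blocks
    for (int rep = 0; rep < (family == 0 ? 0 : 4); ++rep) {
      arma::vec cur(p + M);
      cur.head(p) = beta;
      for (int m = 0; m < M; ++m) cur[p + m] = bmo[m];
      arma::vec prop = blk_beta.propose(cur);
      arma::vec beta_p = prop.head(p);
      arma::vec bmo_p(M);
      for (int m = 0; m < M; ++m) bmo_p[m] = prop[p + m];
      arma::vec eta_fix_p = X * beta_p;
      arma::vec eta_mo_p = arma::zeros(n);
      for (int m = 0; m < M; ++m) eta_mo_p += bmo_p[m] * mo_cols[m];
      arma::vec eta_p = eta_fix_p + eta_mo_p + eta_re;
      double ll_p = loglik_all(eta_p, y, family, tau);
      double lr = ll_p - cur_ll + log_prior_beta(beta_p, bmo_p) - log_prior_beta(beta, bmo);
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        beta = beta_p; bmo = bmo_p;
        eta_fix = eta_fix_p; eta_mo = eta_mo_p; eta = eta_p; cur_ll = ll_p;
        ++accept_beta;
      }
      ++total_beta;
      if (adapting) {
        arma::vec now(p + M);
        now.head(p) = beta;
        for (int m = 0; m < M; ++m) now[p + m] = bmo[m];
        blk_beta.adapt(now, ap, it);
      }
    }

    // ---- monotonic simplexes ----
    for (int m = 0; m < M; ++m) {
      arma::vec prop = blk_gamma[m].propose(gamma[m]);
      arma::vec zeta_p = softmax_simplex(prop);
      arma::vec col_p = mo_column(mo_x[m], zeta_p);
      arma::vec eta_mo_p = eta_mo + bmo[m] * (col_p - mo_cols[m]);
      arma::vec eta_p = eta_fix + eta_mo_p + eta_re;
      double ll_p = loglik_all(eta_p, y, family, tau);
      double lr = ll_p - cur_ll + log_prior_gamma(zeta_p) - log_prior_gamma(zeta[m]);
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        gamma[m] = prop; zeta[m] = zeta_p; mo_cols[m] = col_p;
        eta_mo = eta_mo_p; eta = eta_p; cur_ll = ll_p;
      }
      if (adapting) blk_gamma[m].adapt(gamma[m], ap, it);
    }

    // ---- random intercepts, level by level ----
    for (int f = 0; f < F; ++f) {
      double sd_f = std::exp(log_sd[f]);
      double sc = std::exp(0.5 * re_log_sc[f]);
      double acc_sum = 0.0;
      int L = re_nlev[f];
      for (int l = 0; l < L; ++l) {
        const arma::uvec& rows = level_rows[f][l];
        double cur_u = u[f][l];
        double prop_u = cur_u + sc * R::norm_rand();
        double ll_cur = 0.0, ll_prop = 0.0;
        if (rows.n_elem > 0) {
          ll_cur = loglik_rows(eta, y, family, tau, rows);
          arma::vec eta_p = eta;
          double d = prop_u - cur_u;
          for (arma::uword r = 0; r < rows.n_elem; ++r) eta_p[rows[r]] += d;
          ll_prop = loglik_rows(eta_p, y, family, tau, rows);
        }
        double lr = ll_prop - ll_cur
          + R::dnorm(prop_u, 0.0, sd_f, 1) - R::dnorm(cur_u, 0.0, sd_f, 1);
        double ap = std::min(1.0, std::exp(lr));
        if (R::unif_rand() < ap) {
          double d = prop_u - cur_u;
          u[f][l] = prop_u;
          for (arma::uword r = 0; r < rows.n_elem; ++r) {
            eta_re[rows[r]] += d; eta[rows[r]] += d;
          }
          cur_ll += (ll_prop - ll_cur);
        }
        acc_sum += ap;
      }
      if (adapting) {
        re_t[f] += 1.0;
        double g = std::pow(re_t[f] + 10.0, -0.6);
        re_log_sc[f] += g * (acc_sum / L - TARGET_SCALAR);
      }

      // ---- RE standard deviation (log scale, half-normal(0,1) prior) ----
      double cur_ls = log_sd[f];
      double prop_ls = cur_ls + std::exp(0.5 * sd_log_sc[f]) * R::norm_rand();
      double cur_s = std::exp(cur_ls), prop_s = std::exp(prop_ls);
      double lp_cur = -0.5 * cur_s * cur_s + cur_ls;   // half-normal + Jacobian
      double lp_prop = -0.5 * prop_s * prop_s + prop_ls;
      for (int l = 0; l < L; ++l) {
        lp_cur += R::dnorm(u[f][l], 0.0, cur_s, 1);
        lp_prop += R::dnorm(u[f][l], 0.0, prop_s, 1);
      }
      double ap2 = std::min(1.0, std::exp(lp_prop - lp_cur));
      if (R::unif_rand() < ap2) log_sd[f] = prop_ls;
      if (adapting) {
        sd_t[f] += 1.0;
        double g = std::pow(sd_t[f] + 10.0, -0.6);
        sd_log_sc[f] += g * (ap2 - TARGET_SCALAR);
      }
    }

    // ---- recentering moves: shift a factor's intercepts jointly and
    // compensate in the intercept / cutpoints (likelihood-invariant; breaks
    // the location trade-off between random effects and the intercept) ----
    if (intercept_col >= 0 || family == 1) {
      for (int f = 0; f < F; ++f) {
        double sc = std::exp(0.5 * shift_log_sc[f]);
        double delta = sc * R::norm_rand();
        double sd_f = std::exp(log_sd[f]);
        double lr = 0.0;
        for (int l = 0; l < re_nlev[f]; ++l)
          lr += R::dnorm(u[f][l] + delta, 0.0, sd_f, 1)
              - R::dnorm(u[f][l], 0.0, sd_f, 1);
        if (family == 0) {
          double b0 = beta[intercept_col];
          lr += R::dnorm(b0 - delta, 0.0, beta_prior_sd, 1)
              - R::dnorm(b0, 0.0, beta_prior_sd, 1);
        } else {
          for (int kk = 0; kk < ncut; ++kk)
            lr += R::dnorm(tau[kk] + delta, 0.0, tau_prior_sd, 1)
                - R::dnorm(tau[kk], 0.0, tau_prior_sd, 1);
        }
        double ap = std::min(1.0, std::exp(lr));
        if (R::unif_rand() < ap) {
          for (int l = 0; l < re_nlev[f]; ++l) u[f][l] += delta;
          // eta_re and eta shift by +delta on every row of this factor
          // (every row has some level), compensated exactly:
          if (family == 0) {
            beta[intercept_col] -= delta;
            eta_re += delta; eta_fix -= delta;
          } else {
            for (int kk = 0; kk < ncut; ++kk) tau[kk] += delta;
            dtau[0] = tau[0];
            eta_re += delta; eta += delta;
          }
        }
        if (adapting) {
          shift_t[f] += 1.0;
          double g = std::pow(shift_t[f] + 10.0, -0.6);
          shift_log_sc[f] += g * (ap - TARGET_SCALAR);
        }
      }
    }

    // ---- aligned shifts: for a covariate (near-)constant within a
    // factor's levels, move beta_j and compensate the factor's intercepts
    // by the level means (u_l -= delta * xbar_l). The linear predictor
    // changes only by delta times the within-level residual, so the move
    // walks the beta-vs-intercept ridge that blockwise updates cross very
    // slowly; for exactly level-constant covariates it is
    // likelihood-invariant ----
    for (int s = 0; s < nsh; ++s) {
      int f = shift_factor[s];
      int j = shift_col[s];
      const arma::vec& xl = shift_xlev_v[s];   // level means
      double delta = std::exp(0.5 * al_log_sc[s]) * R::norm_rand();
      double sd_f = std::exp(log_sd[f]);
      double lr = R::dnorm(beta[j] + delta, 0.0, beta_prior_sd, 1)
                - R::dnorm(beta[j], 0.0, beta_prior_sd, 1);
      for (int l = 0; l < re_nlev[f]; ++l)
        lr += R::dnorm(u[f][l] - delta * xl[l], 0.0, sd_f, 1)
            - R::dnorm(u[f][l], 0.0, sd_f, 1);
      double ll_p = cur_ll;
      bool exact = shift_exact[s];
      arma::vec eta_p;
      if (!exact) {
        eta_p = eta + delta * shift_resid[s];
        ll_p = loglik_all(eta_p, y, family, tau);
        lr += ll_p - cur_ll;
      }
      double ap = std::min(1.0, std::exp(lr));
      if (R::unif_rand() < ap) {
        beta[j] += delta;
        for (int l = 0; l < re_nlev[f]; ++l) u[f][l] -= delta * xl[l];
        eta_fix += delta * X.col(j);
        for (int i = 0; i < n; ++i)
          eta_re[i] -= delta * xl[re_idx[f][i]];
        if (!exact) { eta = eta_p; cur_ll = ll_p; }
      }
      if (adapting) {
        al_t[s] += 1.0;
        double g = std::pow(al_t[s] + 10.0, -0.6);
        al_log_sc[s] += g * (ap - TARGET_SCALAR);
      }
    }

    // ---- ordinal cutpoints ----
    if (family == 1) {
      arma::vec prop = blk_tau.propose(dtau);
      arma::vec tau_p(ncut);
      tau_p[0] = prop[0];
      bool ok = true;
      for (int k = 1; k < ncut; ++k) {
        tau_p[k] = tau_p[k - 1] + std::exp(prop[k]);
        if (!std::isfinite(tau_p[k])) ok = false;
      }
      if (ok) {
        double ll_p = loglik_all(eta, y, family, tau_p);
        double lp_cur = 0.0, lp_prop = 0.0;
        for (int k = 0; k < ncut; ++k) {
          lp_cur += R::dnorm(tau[k], 0.0, tau_prior_sd, 1);
          lp_prop += R::dnorm(tau_p[k], 0.0, tau_prior_sd, 1);
        }
        // Jacobian of (tau1, log increments) -> tau
        for (int k = 1; k < ncut; ++k) { lp_cur += dtau[k]; lp_prop += prop[k]; }
        double lr = ll_p - cur_ll + lp_prop - lp_cur;
        double ap = std::min(1.0, std::exp(lr));
        if (R::unif_rand() < ap) { dtau = prop; tau = tau_p; cur_ll = ll_p; }
        if (adapting) blk_tau.adapt(dtau, ap, it);
      }
    }

    // ---- store ----
    if (it >= warmup) {
      int r = it - warmup, c = 0;
      for (int j = 0; j < p; ++j) draws(r, c++) = beta[j];
      for (int m = 0; m < M; ++m) draws(r, c++) = bmo[m];
      for (int m = 0; m < M; ++m)
        for (int d = 0; d < mo_D[m]; ++d) draws(r, c++) = zeta[m][d];
      for (int f = 0; f < F; ++f)
        for (int l = 0; l < re_nlev[f]; ++l) draws(r, c++) = u[f][l];
      for (int f = 0; f < F; ++f) draws(r, c++) = std::exp(log_sd[f]);
      for (int k = 0; k < ncut; ++k) draws(r, c++) = tau[k];
    }

    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws,
    _["accept_rate_fixed"] = (double)accept_beta / total_beta);
}

// [[Rcpp::export]]
double loglik_bernoulli_cpp(arma::vec eta, IntegerVector y) {
  double ll = 0.0;
  for (int i = 0; i < y.size(); ++i) ll += y[i] * eta[i] - log1p_exp(eta[i]);
  return ll;
}

// [[Rcpp::export]]
arma::vec ordinal_probs_cpp(double eta, arma::vec tau) {
  int K = tau.n_elem + 1;
  arma::vec p(K);
  double prev = 0.0;
  for (int k = 0; k < K - 1; ++k) {
    double cum = plogis_(tau[k] - eta);
    p[k] = cum - prev;
    prev = cum;
  }
  p[K - 1] = 1.0 - prev;
  return p;
}
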