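// Gibbs / Metropolis-within-Gibbs sampler for Poisson (log link) and
// Gaussian mixed models with identity- or covariance-structured random
// effects, an observation-level overdispersion (UNIT) term for the Poisson
// family, diffuse normal priors on fixed effects, scaled-F(1,1) priors on
// random-effect variances (via the conjugate inverse-gamma mixture of the
// half-Cauchy) and an inverse-gamma prior on the residual/UNIT variance.
//
// All randomness is drawn from R's RNG so set.seed() on the R side makes
// runs exactly reproducible.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double safe_exp(double x) {
  return std::exp(std::min(x, 30.0));
}

// inverse-gamma(shape, rate) draw using R's RNG
static inline double rinvgamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);  // R::rgamma(shape, scale)
  if (g <= 1e-300) g = 1e-300;
  return 1.0 / g;
}

// [[Rcpp::export]]
List glmm_sampler(const arma::vec& y,
                  int family,              // 0 gaussian, 1 poisson log
                  const arma::mat& X,
                  const List& z_index,     // per random term: 0-based level index per obs
                  const IntegerVector& n_levels,
                  const List& structures,  // per term: R_NilValue (identity) or q x q covariance
                  double fixed_prior_var,
                  double scaledF_scale2,   // squared scale of the F(1,1) prior (1000)
                  double resid_shape, double resid_scale,
                  int n_iter, int burn_in, int thin,
                  bool include_unit,
                  bool prior_only) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = z_index.size();
  const bool gaussian = (family == 0);
  // Gaussian family always has a residual; Poisson has one iff include_unit
  const bool has_resid = gaussian || include_unit;
  const bool mh_path = (!gaussian && !include_unit) && !prior_only;

  // unpack random-term info
  std::vector<arma::uvec> Z(K);
  std::vector<arma::mat> Cinv(K), Cchol(K);
  std::vector<bool> structured(K);
  std::vector<arma::vec> lvl_cnt(K), lvl_ysum(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector zi = z_index[k];
    arma::uvec z(zi.size());
    for (int i = 0; i < zi.size(); ++i) z[i] = zi[i];
    Z[k] = z;
    int q = n_levels[k];
    structured[k] = structures[k] != R_NilValue;
    if (structured[k]) {
      arma::mat C = as<arma::mat>(structures[k]);
      // PSD-repaired matrices can be singular; ridge for inversion only
      arma::mat Cr = C + arma::eye(q, q) * 1e-8;
      Cinv[k] = arma::inv_sympd(Cr);
      Cchol[k] = arma::chol(Cr, "lower");
    }
    arma::vec cnt(q, arma::fill::zeros), ys(q, arma::fill::zeros);
    for (int i = 0; i < n; ++i) { cnt[z[i]] += 1.0; ys[z[i]] += y[i]; }
    lvl_cnt[k] = cnt; lvl_ysum[k] = ys;
  }

  // state
  arma::vec beta(p, arma::fill::zeros);
  if (p > 0 && !prior_only) {
    double m = arma::mean(y);
    beta[0] = gaussian ? m : std::log(std::max(m, 1e-3));
  }
  std::vector<arma::vec> u(K);
  for (int k = 0; k < K; ++k) u[k] = arma::vec(n_levels[k], arma::fill::zeros);
  arma::vec sigma2(K, arma::fill::ones); sigma2 *= 0.1;
  arma::vec a_aux(K, arma::fill::ones);
  double sigma2_e = gaussian ? std::max(arma::var(y) / 2.0, 1e-6) : 0.5;

  // m = X beta + sum_k u_k[z]  (linear predictor excluding UNIT term)
  arma::vec m = X * beta;
  // latent log-rate eta = m + UNIT effect; for the Gaussian family eta = y.
  // Location updates condition on eta (the Gaussian-layer "data"), so the
  // UNIT residual eta - m changes implicitly as m moves.
  arma::vec eta = gaussian ? y : m;

  // adaptive random-walk steps
  double step_e = 0.5;
  arma::vec step_beta(p, arma::fill::value(0.1));
  arma::vec step_u(K, arma::fill::value(0.2));
  long acc_e = 0, try_e = 0;
  arma::vec acc_beta(p, arma::fill::zeros), try_beta(p, arma::fill::zeros);
  arma::vec acc_u(K, arma::fill::zeros), try_u(K, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat out_beta(n_keep, p, arma::fill::zeros);
  arma::mat out_sigma(n_keep, K + (has_resid ? 1 : 0), arma::fill::zeros);
  int keep = 0;

  GetRNGstate();
  for (int iter = 1; iter <= n_iter; ++iter) {
    if (!prior_only) {
      if (!mh_path) {
        // ---- Gaussian layer: w is the latent (or observed) response ----
        // w = m + e for poisson+unit; w = y for gaussian
        // update beta | rest (conjugate)
        if (p > 0) {
          arma::vec Xb = X * beta;
          arma::vec r = eta - (m - Xb);  // eta minus the random-effect part
          arma::mat P = X.t() * X / sigma2_e;
          P.diag() += 1.0 / fixed_prior_var;
          arma::vec b = X.t() * r / sigma2_e;
          arma::mat U = arma::chol(P);
          arma::vec mu = arma::solve(P, b, arma::solve_opts::likely_sympd);
          arma::vec zdraw(p);
          for (int j = 0; j < p; ++j) zdraw[j] = norm_rand();
          arma::vec beta_new = mu + arma::solve(arma::trimatu(U), zdraw);
          m += X * (beta_new - beta);
          beta = beta_new;
        }
        // update each random term (conjugate given w)
        for (int k = 0; k < K; ++k) {
          int q = n_levels[k];
          // residual against all terms except k: s_l = sum over level of
          // (eta - m + u_k[z]); eta - m excludes nothing, so add u_k back
          arma::vec S(q, arma::fill::zeros);
          const arma::uvec& z = Z[k];
          for (int i = 0; i < n; ++i) S[z[i]] += eta[i] - m[i];
          S += lvl_cnt[k] % u[k];
          arma::vec u_new(q);
          if (!structured[k]) {
            for (int l = 0; l < q; ++l) {
              double prec = lvl_cnt[k][l] / sigma2_e + 1.0 / sigma2[k];
              double mu_l = (S[l] / sigma2_e) / prec;
              u_new[l] = mu_l + norm_rand() / std::sqrt(prec);
            }
          } else {
            arma::mat P = Cinv[k] / sigma2[k];
            P.diag() += lvl_cnt[k] / sigma2_e;
            arma::vec b = S / sigma2_e;
            arma::vec mu = arma::solve(P, b, arma::solve_opts::likely_sympd);
            arma::mat U = arma::chol(P);
            arma::vec zdraw(q);
            for (int l = 0; l < q; ++l) zdraw[l] = norm_rand();
            u_new = mu + arma::solve(arma::trimatu(U), zdraw);
          }
          arma::vec delta = u_new - u[k];
          for (int i = 0; i < n; ++i) m[i] += delta[z[i]];
          u[k] = u_new;
        }
        if (!gaussian) {
          // ---- MH update of the latent log-rates given the Poisson data ----
          for (int i = 0; i < n; ++i) {
            double prop = eta[i] + step_e * norm_rand();
            double r_new = prop - m[i], r_old = eta[i] - m[i];
            double lr = y[i] * (prop - eta[i])
              - (safe_exp(prop) - safe_exp(eta[i]))
              - (r_new * r_new - r_old * r_old) / (2.0 * sigma2_e);
            ++try_e;
            if (std::log(unif_rand()) < lr) { eta[i] = prop; ++acc_e; }
          }
        }
      } else {
        // ---- MH path: Poisson without UNIT term ----
        arma::vec expm(n);
        for (int i = 0; i < n; ++i) expm[i] = safe_exp(m[i]);
        for (int j = 0; j < p; ++j) {
          double d = step_beta[j] * norm_rand();
          double t1 = 0, t2 = 0;
          for (int i = 0; i < n; ++i) { t1 += y[i] * X(i, j) * d;
            t2 += expm[i] * (safe_exp(X(i, j) * d) - 1.0); }
          double lr = t1 - t2
            - ((beta[j] + d) * (beta[j] + d) - beta[j] * beta[j]) / (2.0 * fixed_prior_var);
          ++try_beta[j];
          if (std::log(unif_rand()) < lr) {
            beta[j] += d;
            for (int i = 0; i < n; ++i) { m[i] += X(i, j) * d; expm[i] *= safe_exp(X(i, j) * d); }
            ++acc_beta[j];
          }
        }
        for (int k = 0; k < K; ++k) {
          int q = n_levels[k];
          const arma::uvec& z = Z[k];
          arma::vec T2(q, arma::fill::zeros);
          for (int i = 0; i < n; ++i) T2[z[i]] += expm[i];
          arma::vec Qu;
          if (structured[k]) Qu = (Cinv[k] * u[k]) / sigma2[k];
          arma::vec delta(q, arma::fill::zeros);
          for (int l = 0; l < q; ++l) {
            double d = step_u[k] * norm_rand();
            double pr_old, pr_new;
            if (!structured[k]) {
              pr_old = -u[k][l] * u[k][l] / (2.0 * sigma2[k]);
              pr_new = -(u[k][l] + d) * (u[k][l] + d) / (2.0 * sigma2[k]);
            } else {
              double Qll = Cinv[k](l, l) / sigma2[k];
              double cross = Qu[l] - Qll * u[k][l];
              double mu_l = -cross / Qll;
              pr_old = -Qll * (u[k][l] - mu_l) * (u[k][l] - mu_l) / 2.0;
              pr_new = -Qll * (u[k][l] + d - mu_l) * (u[k][l] + d - mu_l) / 2.0;
            }
            double lr = lvl_ysum[k][l] * d - T2[l] * (safe_exp(d) - 1.0)
              + pr_new - pr_old;
            ++try_u[k];
            if (std::log(unif_rand()) < lr) { delta[l] = d; ++acc_u[k]; }
          }
          bool any = arma::any(delta != 0.0);
          if (any) {
            u[k] += delta;
            for (int i = 0; i < n; ++i)
              if (delta[z[i]] != 0.0) { m[i] += delta[z[i]]; expm[i] *= safe_exp(delta[z[i]]); }
            if (structured[k]) Qu = (Cinv[k] * u[k]) / sigma2[k];
          }
        }
      }
    } else {
      // prior-only: draw u from its conditional prior
      for (int k = 0; k < K; ++k) {
        int q = n_levels[k];
        arma::vec zdraw(q);
        for (int l = 0; l < q; ++l) zdraw[l] = norm_rand();
        u[k] = structured[k] ? arma::vec(Cchol[k] * zdraw * std::sqrt(sigma2[k]))
                             : arma::vec(zdraw * std::sqrt(sigma2[k]));
      }
    }

    // ---- variance updates ----
    for (int k = 0; k < K; ++k) {
      int q = n_levels[k];
      double ss = structured[k]
        ? arma::as_scalar(u[k].t() * Cinv[k] * u[k])
        : arma::dot(u[k], u[k]);
      sigma2[k] = rinvgamma((q + 1.0) / 2.0, 1.0 / a_aux[k] + ss / 2.0);
      a_aux[k] = rinvgamma(1.0, 1.0 / scaledF_scale2 + 1.0 / sigma2[k]);
    }
    if (has_resid && !prior_only && !mh_path) {
      arma::vec r = eta - m;
      double ss = arma::dot(r, r);
      sigma2_e = rinvgamma(resid_shape + n / 2.0, resid_scale + ss / 2.0);
    }

    // ---- adaptation during burn-in ----
    if (iter <= burn_in && iter % 100 == 0) {
      if (try_e > 0) {
        double rate = (double)acc_e / (double)try_e;
        step_e *= std::exp(std::min(std::max(0.7 * (rate - 0.35), -0.5), 0.5));
        acc_e = 0; try_e = 0;
      }
      for (int j = 0; j < p; ++j) if (try_beta[j] > 0) {
        double rate = acc_beta[j] / try_beta[j];
        step_beta[j] *= std::exp(std::min(std::max(0.7 * (rate - 0.35), -0.5), 0.5));
        acc_beta[j] = 0; try_beta[j] = 0;
      }
      for (int k = 0; k < K; ++k) if (try_u[k] > 0) {
        double rate = acc_u[k] / try_u[k];
        step_u[k] *= std::exp(std::min(std::max(0.7 * (rate - 0.35), -0.5), 0.5));
        acc_u[k] = 0; try_u[k] = 0;
      }
    }

    // ---- storage ----
    if (iter > burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) out_beta(keep, j) = beta[j];
      for (int k = 0; k < K; ++k) out_sigma(keep, k) = sigma2[k];
      if (has_resid) out_sigma(keep, K) = sigma2_e;
      ++keep;
    }
    if (iter % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  double acc_rate_e = try_e > 0 ? (double)acc_e / (double)try_e : NA_REAL;
  return List::create(
    _["beta"] = out_beta,
    _["sigma2"] = out_sigma,
    _["accept_unit"] = acc_rate_e,
    _["step_unit"] = step_e,
    _["n_keep"] = keep);
}
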