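// Gibbs samplers: (1) Bayesian animal model with batch and up to three
// correlated genetic effects sampled in their kernel eigenbases;
// (2) BayesB whole-genome regression with a point-mass + scaled-t mixture
// prior on marker effects. Both use R's RNG so set.seed() governs chains.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvchisq(double df, double scale) {
  // scaled inverse chi-square: df * scale / chisq(df)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_animal_cpp")]]
List gibbs_animal_cpp(const arma::vec& y,
                      const arma::mat& X,
                      const arma::ivec& batch,   // 1-based, 0 = no batch term
                      int n_batch,
                      const List& eigvecs,       // list of U (n x n)
                      const List& eigvals,       // list of lambda (n)
                      double prior_df,
                      const arma::vec& kernel_prior_scale,
                      double batch_prior_scale,
                      double resid_prior_scale,
                      int n_iter, int burn_in, int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int nk = eigvecs.size();
  const bool has_batch = n_batch > 0;

  std::vector<arma::mat> U(nk);
  std::vector<arma::vec> lam(nk);
  for (int k = 0; k < nk; ++k) {
    U[k] = as<arma::mat>(eigvecs[k]);
    lam[k] = as<arma::vec>(eigvals[k]);
  }

  arma::mat XtX = X.t() * X;
  arma::mat XtXinv = arma::inv_sympd(XtX);
  arma::mat Lfix = arma::chol(XtXinv, "lower");

  // batch bookkeeping
  std::vector<std::vector<int>> bidx(n_batch);
  if (has_batch)
    for (int i = 0; i < n; ++i) bidx[batch[i] - 1].push_back(i);

  // state
  arma::vec b(p, arma::fill::zeros);
  arma::vec h(std::max(n_batch, 1), arma::fill::zeros);
  std::vector<arma::vec> eff(nk, arma::vec(n, arma::fill::zeros));
  arma::vec sig2k(std::max(nk, 1));
  for (int k = 0; k < nk; ++k) sig2k[k] = kernel_prior_scale[k];
  double sig2h = has_batch ? batch_prior_scale : 0.0;
  double sig2e = resid_prior_scale;

  const int n_ret = (n_iter - burn_in) / thin;
  arma::mat var_samples(n_ret, nk + 2, arma::fill::zeros);
  arma::mat b_samples(n_ret, p, arma::fill::zeros);
  arma::vec b_mean(p, arma::fill::zeros);
  arma::vec h_mean(std::max(n_batch, 1), arma::fill::zeros);
  arma::mat eff_mean(n, std::max(nk, 1), arma::fill::zeros);
  int kept = 0, accum = 0;

  const double lam_tol = 1e-10;

  arma::vec Xb = X * b;
  arma::vec Wh(n, arma::fill::zeros);

  for (int it = 0; it < n_iter; ++it) {
    // total genetic signal
    arma::vec gsum(n, arma::fill::zeros);
    for (int k = 0; k < nk; ++k) gsum += eff[k];

    // fixed effects: b | rest
    {
      arma::vec r = y - Wh - gsum;
      arma::vec mu = XtXinv * (X.t() * r);
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      b = mu + std::sqrt(sig2e) * (Lfix * z);
      Xb = X * b;
    }

    // batch effects
    if (has_batch) {
      arma::vec r = y - Xb - gsum;
      for (int j = 0; j < n_batch; ++j) {
        double s = 0.0;
        for (int idx : bidx[j]) s += r[idx];
        double nj = (double)bidx[j].size();
        double prec = nj / sig2e + 1.0 / sig2h;
        double m = (s / sig2e) / prec;
        h[j] = m + R::norm_rand() / std::sqrt(prec);
      }
      for (int i = 0; i < n; ++i) Wh[i] = h[batch[i] - 1];
      // batch variance
      double ssh = arma::dot(h.head(n_batch), h.head(n_batch));
      sig2h = (ssh + prior_df * batch_prior_scale) /
              R::rchisq((double)n_batch + prior_df);
    }

    // correlated genetic effects, each in its kernel eigenbasis
    for (int k = 0; k < nk; ++k) {
      gsum -= eff[k];
      arma::vec r = y - Xb - Wh - gsum;
      arma::vec t = U[k].t() * r;
      arma::vec a_t(n);
      double ss = 0.0; int rank = 0;
      for (int i = 0; i < n; ++i) {
        double l = lam[k][i];
        if (l <= lam_tol) { a_t[i] = 0.0; continue; }
        double v = 1.0 / (1.0 / sig2e + 1.0 / (l * sig2k[k]));
        double m = v * t[i] / sig2e;
        a_t[i] = m + R::norm_rand() * std::sqrt(v);
        ss += a_t[i] * a_t[i] / l;
        ++rank;
      }
      eff[k] = U[k] * a_t;
      sig2k[k] = (ss + prior_df * kernel_prior_scale[k]) /
                 R::rchisq((double)rank + prior_df);
      gsum += eff[k];
    }

    // residual variance
    {
      arma::vec e = y - Xb - Wh - gsum;
      double sse = arma::dot(e, e);
      sig2e = (sse + prior_df * resid_prior_scale) /
              R::rchisq((double)n + prior_df);
    }

    if (it >= burn_in) {
      ++accum;
      b_mean += b;
      if (has_batch) h_mean += h;
      for (int k = 0; k < nk; ++k) eff_mean.col(k) += eff[k];
      if ((it - burn_in) % thin == 0 && kept < n_ret) {
        for (int k = 0; k < nk; ++k) var_samples(kept, k) = sig2k[k];
        var_samples(kept, nk) = has_batch ? sig2h : NA_REAL;
        var_samples(kept, nk + 1) = sig2e;
        b_samples.row(kept) = b.t();
        ++kept;
      }
    }
  }

  b_mean /= std::max(accum, 1);
  h_mean /= std::max(accum, 1);
  eff_mean /= std::max(accum, 1);

  return List::create(_["var_samples"] = var_samples,
                      _["b_samples"] = b_samples,
                      _["b_mean"] = b_mean,
                      _["h_mean"] = h_mean,
                      _["effect_means"] = eff_mean,
                      _["n_retained"] = kept);
}

// [[Rcpp::export(name = ".bayesb_cpp")]]
List bayesb_cpp(const arma::vec& y,
                const arma::mat& M,      // centered marker matrix
                double pi0,              // prior null probability
                double df, double SB,    // scaled-t: df and scale
                int n_iter, int burn_in, int thin,
                bool intercept,
                double fixed_sig2e,      // > 0 fixes the residual variance
                double resid_df, double resid_scale) {
  const int n = y.n_elem;
  const int m = M.n_cols;

  arma::vec mww(m);
  for (int w = 0; w < m; ++w) mww[w] = arma::dot(M.col(w), M.col(w));

  double mu = intercept ? arma::mean(y) : 0.0;
  arma::vec u(m, arma::fill::zeros);
  arma::vec sig2w(m);
  for (int w = 0; w < m; ++w) sig2w[w] = SB * df / std::max(df - 2.0, 0.5);
  double sig2e = fixed_sig2e > 0 ? fixed_sig2e : resid_scale;

  arma::vec e = y - mu;  // residual given current state (u = 0)

  const int n_ret = (n_iter - burn_in) / thin;
  arma::vec u_mean(m, arma::fill::zeros);
  double mu_mean = 0.0;
  arma::vec sig2e_samples(n_ret, arma::fill::zeros);
  arma::vec nnz_samples(n_ret, arma::fill::zeros);
  arma::mat u_samples;
  bool store_u = (m <= 16);  // small fixtures only (oracle tests)
  if (store_u) u_samples.set_size(n_ret, m);
  int kept = 0, accum = 0;
  const double log_prior_odds =
      (pi0 >= 1.0) ? -INFINITY
                   : std::log(1.0 - pi0) - std::log(std::max(pi0, 1e-300));

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    if (intercept) {
      double s = (arma::accu(e) + n * mu) / n;  // mean of y - Mu
      double newmu = s + R::norm_rand() * std::sqrt(sig2e / n);
      e += (mu - newmu);
      mu = newmu;
    }

    int nnz = 0;
    for (int w = 0; w < m; ++w) {
      // residual without marker w
      if (u[w] != 0.0) e += M.col(w) * u[w];
      double rhs = arma::dot(M.col(w), e);
      bool incl;
      if (pi0 >= 1.0) {
        incl = false;
      } else if (pi0 <= 0.0) {
        incl = true;
      } else {
        double A = mww[w] / sig2e + 1.0 / sig2w[w];
        double log_ratio = -0.5 * std::log1p(mww[w] * sig2w[w] / sig2e) +
                           rhs * rhs / (2.0 * sig2e * sig2e * A);
        double logit = log_prior_odds + log_ratio;
        double pr = 1.0 / (1.0 + std::exp(-logit));
        incl = (R::unif_rand() < pr);
      }
      if (incl) {
        double C = mww[w] + sig2e / sig2w[w];
        double mean_u = rhs / C;
        double var_u = sig2e / C;
        u[w] = mean_u + R::norm_rand() * std::sqrt(var_u);
        e -= M.col(w) * u[w];
        ++nnz;
        sig2w[w] = rinvchisq(df + 1.0,
                             (u[w] * u[w] + df * SB) / (df + 1.0));
      } else {
        u[w] = 0.0;
        sig2w[w] = rinvchisq(df, SB);  // refresh from the prior
      }
    }

    if (fixed_sig2e <= 0) {
      double sse = arma::dot(e, e);
      sig2e = (sse + resid_df * resid_scale) /
              R::rchisq((double)n + resid_df);
    }

    if (it >= burn_in) {
      ++accum;
      u_mean += u;
      mu_mean += mu;
      if ((it - burn_in) % thin == 0 && kept < n_ret) {
        sig2e_samples[kept] = sig2e;
        nnz_samples[kept] = nnz;
        if (store_u) u_samples.row(kept) = u.t();
        ++kept;
      }
    }
  }

  u_mean /= std::max(accum, 1);
  mu_mean /= std::max(accum, 1);

  List out = List::create(_["u_mean"] = u_mean,
                          _["mu_mean"] = mu_mean,
                          _["sig2e_samples"] = sig2e_samples,
                          _["nnz_samples"] = nnz_samples,
                          _["n_retained"] = kept);
  if (store_u) out["u_samples"] = u_samples;
  return out;
}
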