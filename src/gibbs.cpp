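// Gibbs sampler for the multi-kernel Bayesian linear mixed model
//   y = X mu + sum_k B_k a_k + e,
// where X holds treatment dummies with flat priors, each component k is a
// kernel-structured random effect sampled in the eigenbasis of its kernel
// (B_k = M V, prior a_kr ~ N(0, d_kr * sigma2_k)), and every variance has a
// scaled-inverse-chi-square prior. Coordinates whose basis column carries no
// data (e.g. the line effect of a held-out line) are drawn from their prior,
// which is how predictions for unphenotyped lines arise.
//
// Uses R's RNG throughout so chains are reproducible from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double sample_var(const arma::vec& v) {
  if (v.n_elem < 2) return 0.0;
  return arma::var(v); // n-1 denominator
}

// [[Rcpp::export(name = ".gibbs_multikernel")]]
List gibbs_multikernel(const arma::vec& y,
                       const arma::mat& X,
                       const List& B_list,
                       const List& d_list,
                       const List& Bp_list,
                       const arma::mat& Xp,
                       const arma::vec& df0,
                       const arma::vec& S0,
                       double df0_e,
                       double S0_e,
                       int n_iter,
                       int burn_in,
                       int thin,
                       bool store_effects) {
  const int n = y.n_elem;
  const int p = X.n_cols;
  const int K = B_list.size();
  const int np = Xp.n_rows;
  const int n_store = (n_iter - burn_in) / thin;

  std::vector<arma::mat> B(K), Bp(K);
  std::vector<arma::vec> d(K), a(K), bnorm2(K);
  arma::vec qk(K);
  for (int k = 0; k < K; ++k) {
    B[k] = as<arma::mat>(B_list[k]);
    Bp[k] = as<arma::mat>(Bp_list[k]);
    d[k] = as<arma::vec>(d_list[k]);
    a[k] = arma::zeros(B[k].n_cols);
    bnorm2[k] = arma::sum(arma::square(B[k]), 0).t();
    qk(k) = B[k].n_cols;
  }

  arma::vec xtx = arma::sum(arma::square(X), 0).t();
  arma::vec mu = arma::zeros(p);
  for (int j = 0; j < p; ++j) {
    if (xtx(j) > 0) mu(j) = arma::dot(X.col(j), y) / xtx(j);
  }
  arma::vec e = y - X * mu;
  double vy = sample_var(y);
  arma::vec s2 = S0 * df0(0) / (df0(0) + 2.0); // start at prior modes
  for (int k = 0; k < K; ++k) {
    s2(k) = S0(k) * df0(k) / (df0(k) + 2.0);
    if (s2(k) <= 0) s2(k) = 0.1 * vy;
  }
  double s2e = 0.5 * vy;

  arma::mat mu_store(n_store, p);
  arma::mat s2_store(n_store, K + 1);
  arma::mat cv_store(n_store, K + 1); // fixed-part variance + per-component
  arma::vec ll_store(n_store);
  arma::vec yhat = arma::zeros(np);
  arma::mat comp_pred = arma::zeros(np, K + 1);
  List eff_store(K);
  std::vector<arma::mat> eff(K);
  if (store_effects) {
    for (int k = 0; k < K; ++k) eff[k] = arma::mat(n_store, n);
  }

  int s = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // fixed effects (flat prior)
    for (int j = 0; j < p; ++j) {
      if (xtx(j) <= 0) continue;
      double rhs = arma::dot(X.col(j), e) + xtx(j) * mu(j);
      double mean = rhs / xtx(j);
      double newv = R::rnorm(mean, std::sqrt(s2e / xtx(j)));
      e -= X.col(j) * (newv - mu(j));
      mu(j) = newv;
    }
    // kernel / iid components, coordinate-wise
    for (int k = 0; k < K; ++k) {
      arma::vec& ak = a[k];
      const arma::mat& Bk = B[k];
      const arma::vec& dk = d[k];
      const arma::vec& b2 = bnorm2[k];
      for (arma::uword r = 0; r < ak.n_elem; ++r) {
        double prior_prec = 1.0 / (dk(r) * s2(k));
        double bb = b2(r);
        if (bb > 0) {
          double prec = bb / s2e + prior_prec;
          double rhs = (arma::dot(Bk.col(r), e) + bb * ak(r)) / s2e;
          double newv = R::rnorm(rhs / prec, 1.0 / std::sqrt(prec));
          e -= Bk.col(r) * (newv - ak(r));
          ak(r) = newv;
        } else {
          ak(r) = R::rnorm(0.0, std::sqrt(dk(r) * s2(k)));
        }
      }
      double ss = arma::sum(arma::square(ak) / dk);
      s2(k) = (ss + df0(k) * S0(k)) / R::rchisq(df0(k) + qk(k));
    }
    // residual variance
    s2e = (arma::dot(e, e) + df0_e * S0_e) / R::rchisq(df0_e + n);

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      mu_store.row(s) = mu.t();
      for (int k = 0; k < K; ++k) s2_store(s, k) = s2(k);
      s2_store(s, K) = s2e;
      arma::vec fixed = X * mu;
      cv_store(s, 0) = sample_var(fixed);
      arma::vec yp = Xp * mu;
      comp_pred.col(0) += Xp * mu;
      for (int k = 0; k < K; ++k) {
        arma::vec uk = B[k] * a[k];
        cv_store(s, k + 1) = sample_var(uk);
        arma::vec ukp = Bp[k] * a[k];
        yp += ukp;
        comp_pred.col(k + 1) += ukp;
        if (store_effects) eff[k].row(s) = uk.t();
      }
      yhat += yp;
      ll_store(s) = -0.5 * n * std::log(2.0 * M_PI * s2e)
        - 0.5 * arma::dot(e, e) / s2e;
      ++s;
    }
  }
  yhat /= n_store;
  comp_pred /= n_store;
  if (store_effects) {
    for (int k = 0; k < K; ++k) eff_store[k] = eff[k];
  }
  return List::create(_["mu"] = mu_store,
                      _["sigma2"] = s2_store,
                      _["comp_var"] = cv_store,
                      _["loglik"] = ll_store,
                      _["yhat"] = yhat,
                      _["comp_pred"] = comp_pred,
                      _["effects"] = eff_store);
}
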