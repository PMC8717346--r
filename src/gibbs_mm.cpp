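// Blocked Gibbs sampler for a Gaussian mixed model with nested random
// intercepts, an optional phylogenetically structured component, and
// non-central parameter expansion on the variance priors:
//
//   y = X beta + sum_k alpha_k Z_k u_k + e,
//   u_k ~ N(0, s2_k A_k),  e ~ N(0, s2e I),
//   s2 ~ scaled-inv-chi^2(nu, V),  alpha_k ~ N(alpha_mu, alpha_V).
//
// Steps per iteration: (i) (beta, u) jointly from the multivariate normal
// full conditional; (ii) each s2_k from its scaled-inverse-chi-square full
// conditional (A_k^{-1} = C^{-1} for the phylogenetic component);
// (iii) each working parameter alpha_k from a scalar normal; (iv) s2e.
// Uses R's RNG throughout, so chains are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = norm_rand();
  return z;
}

// [[Rcpp::export]]
List gibbs_mm_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                  const arma::ivec& qk, const List& Ainv_list,
                  const arma::vec& Vk, const arma::vec& nuk,
                  const arma::vec& alpha_mu, const arma::vec& alpha_V,
                  const arma::ivec& px,
                  double resid_V, double resid_nu, double beta_prior_var,
                  int niter, int burnin, int thin) {
  const int n = y.n_elem, p = X.n_cols, K = qk.n_elem;
  int q = 0;
  for (int k = 0; k < K; ++k) q += qk[k];
  const int t = p + q;

  arma::mat W(n, t);
  W.cols(0, p - 1) = X;
  if (q > 0) W.cols(p, t - 1) = Z;
  const arma::mat WtW = W.t() * W;
  const arma::vec Wty = W.t() * y;

  // block offsets into theta
  arma::ivec off(K + 1);
  off[0] = p;
  for (int k = 0; k < K; ++k) off[k + 1] = off[k] + qk[k];

  std::vector<arma::mat> Ainv(K);
  std::vector<bool> ident(K, true);
  std::vector<arma::mat> Zk(K);
  for (int k = 0; k < K; ++k) {
    if (Ainv_list[k] != R_NilValue) {
      Ainv[k] = as<arma::mat>(Ainv_list[k]);
      ident[k] = false;
    }
    Zk[k] = Z.cols(off[k] - p, off[k + 1] - 1 - p);
  }

  arma::vec theta(t, arma::fill::zeros);
  arma::vec s2(K);
  arma::vec alpha(K, arma::fill::ones);
  for (int k = 0; k < K; ++k) s2[k] = Vk[k];
  double s2e = arma::var(y);
  if (!(s2e > 0)) s2e = 1.0;

  const int nstore = (niter - burnin) / thin;
  arma::mat Sol(nstore, p);
  arma::mat VCV(nstore, K + 1);
  arma::vec dev(nstore);
  arma::vec eta_sum(n, arma::fill::zeros);
  const double LOG2PI = std::log(2.0 * M_PI);

  arma::vec Dv(t, arma::fill::ones);
  arma::mat M(t, t);
  arma::vec b(t), mu(t), e(n), eta(n);
  int stored = 0;

  for (int it = 1; it <= niter; ++it) {
    // scaling vector from current alphas
    for (int k = 0; k < K; ++k)
      Dv.subvec(off[k], off[k + 1] - 1).fill(alpha[k]);

    // (i) joint (beta, u) draw
    M = WtW;
    M.each_col() %= Dv;
    M.each_row() %= Dv.t();
    M /= s2e;
    for (int i = 0; i < p; ++i) M(i, i) += 1.0 / beta_prior_var;
    for (int k = 0; k < K; ++k) {
      if (ident[k]) {
        for (int i = off[k]; i < off[k + 1]; ++i) M(i, i) += 1.0 / s2[k];
      } else {
        M.submat(off[k], off[k], off[k + 1] - 1, off[k + 1] - 1) +=
          Ainv[k] / s2[k];
      }
    }
    b = (Wty % Dv) / s2e;
    arma::mat R;
    if (!arma::chol(R, M))
      stop("Cholesky failure in the joint full conditional");
    mu = arma::solve(arma::trimatu(R),
                     arma::solve(arma::trimatl(R.t()), b));
    theta = mu + arma::solve(arma::trimatu(R), rnorm_vec(t));

    // (ii) variance components
    for (int k = 0; k < K; ++k) {
      arma::vec u = theta.subvec(off[k], off[k + 1] - 1);
      double ss = ident[k] ? arma::dot(u, u)
                           : arma::as_scalar(u.t() * Ainv[k] * u);
      double df = nuk[k] + qk[k];
      s2[k] = (nuk[k] * Vk[k] + ss) / ::Rf_rchisq(df);
      if (s2[k] > 1e12)
        stop("sampler divergence: variance component exceeded 1e12");
    }

    // (iii) working parameters alpha_k
    arma::vec xb = X * theta.head(p);
    std::vector<arma::vec> Zu(K);
    arma::vec fit_all = xb;
    for (int k = 0; k < K; ++k) {
      Zu[k] = Zk[k] * theta.subvec(off[k], off[k + 1] - 1);
      fit_all += alpha[k] * Zu[k];
    }
    for (int k = 0; k < K; ++k) {
      if (!px[k]) continue;
      arma::vec r = y - fit_all + alpha[k] * Zu[k];
      double prec = arma::dot(Zu[k], Zu[k]) / s2e + 1.0 / alpha_V[k];
      double m = (arma::dot(Zu[k], r) / s2e + alpha_mu[k] / alpha_V[k]) / prec;
      double a_new = m + norm_rand() / std::sqrt(prec);
      fit_all += (a_new - alpha[k]) * Zu[k];
      alpha[k] = a_new;
    }

    // (iv) residual variance
    eta = fit_all;
    e = y - eta;
    s2e = (resid_nu * resid_V + arma::dot(e, e)) /
          ::Rf_rchisq(resid_nu + n);
    if (s2e > 1e12)
      stop("sampler divergence: residual variance exceeded 1e12");

    // record
    if (it > burnin && (it - burnin) % thin == 0 && stored < nstore) {
      for (int i = 0; i < p; ++i) Sol(stored, i) = theta[i];
      for (int k = 0; k < K; ++k)
        VCV(stored, k) = alpha[k] * alpha[k] * s2[k];
      VCV(stored, K) = s2e;
      dev[stored] = n * (LOG2PI + std::log(s2e)) + arma::dot(e, e) / s2e;
      eta_sum += eta;
      ++stored;
    }
  }

  return List::create(_["Sol"] = Sol, _["VCV"] = VCV, _["deviance"] = dev,
                      _["eta_mean"] = eta_sum / std::max(stored, 1),
                      _["n_stored"] = stored);
}
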