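// EM for full-covariance Gaussian mixtures with MAP covariance shrinkage.
// Restarts, k-means initialization and seeding stay on the R side; this is
// only the (deterministic) inner loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_gmm_em(const arma::mat& X, arma::ivec init, int k,
                const arma::mat& prior, double nu,
                int max_iter, double tol) {
  int n = X.n_rows, d = X.n_cols;
  arma::vec w(k);
  arma::mat mu(k, d);
  std::vector<arma::mat> sig(k);

  // init from hard assignments (1-based)
  for (int j = 0; j < k; ++j) {
    arma::uvec idx = arma::find(init == j + 1);
    if (idx.n_elem < 2) {
      // degenerate init: fall back to the global moments
      w(j) = 1.0 / k;
      mu.row(j) = arma::mean(X, 0);
      sig[j] = (arma::cov(X, 1) * n + nu * prior) / (n + nu);
      continue;
    }
    w(j) = (double)idx.n_elem / n;
    arma::mat Xj = X.rows(idx);
    mu.row(j) = arma::mean(Xj, 0);
    sig[j] = (arma::cov(Xj, 1) * idx.n_elem + nu * prior) / (idx.n_elem + nu);
  }
  w /= arma::accu(w);

  arma::mat logdens(n, k);
  arma::mat resp(n, k);
  double ll = -arma::datum::inf, ll_old = -arma::datum::inf;
  const double l2pi = std::log(2.0 * M_PI);

  for (int it = 0; it < max_iter; ++it) {
    // E-step in log space
    for (int j = 0; j < k; ++j) {
      arma::mat R;
      if (!arma::chol(R, sig[j])) return List::create(Named("ok") = false);
      double logdet = 2.0 * arma::accu(arma::log(R.diag()));
      arma::mat Z = arma::solve(arma::trimatl(R.t()),
                                (X.each_row() - mu.row(j)).t());
      arma::rowvec q = arma::sum(arma::square(Z), 0);
      logdens.col(j) = (std::log(w(j)) - 0.5 * (d * l2pi + logdet)
                        - 0.5 * q.t());
    }
    arma::vec m = arma::max(logdens, 1);
    arma::mat e = arma::exp(logdens.each_col() - m);
    arma::vec rs = arma::sum(e, 1);
    ll = arma::accu(m + arma::log(rs));
    resp = e.each_col() / rs;

    if (std::abs(ll - ll_old) < tol * (std::abs(ll) + 1.0)) break;
    ll_old = ll;

    // M-step with covariance shrinkage toward the prior
    arma::rowvec nk = arma::sum(resp, 0);
    if (nk.min() < 1e-8) return List::create(Named("ok") = false);
    w = nk.t() / n;
    for (int j = 0; j < k; ++j) {
      mu.row(j) = (resp.col(j).t() * X) / nk(j);
      arma::mat Xc = X.each_row() - mu.row(j);
      Xc.each_col() %= arma::sqrt(resp.col(j));
      sig[j] = (Xc.t() * Xc + nu * prior) / (nk(j) + nu);
    }
  }
  List sigl(k);
  for (int j = 0; j < k; ++j) sigl[j] = sig[j];
  return List::create(Named("ok") = true, Named("w") = w,
                      Named("mu") = mu, Named("sig") = sigl,
                      Named("ll") = ll, Named("resp") = resp);
}
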