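// Panel simulated log-likelihood for the error-component logit.
//
// Each row of D is the dummy-coded difference x_A - x_B for one choice task;
// s is +1 when alternative A was chosen and -1 otherwise, so the chosen
// alternative's probability is plogis(s * (dV + sigma * eta)), with eta the
// respondent's error-component draw (attached to alternative A only).
// The per-respondent likelihood is the product over tasks averaged over the
// draws in eta; the function returns the sum of the logs of these averages,
// its analytic gradient and, when requested, per-respondent score
// contributions (used for clustered sandwich covariances).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List ecl_msl_core(const arma::vec& par, const arma::mat& D, const arma::vec& s,
                  const arma::uvec& resp, const arma::mat& eta,
                  const bool want_grad, const bool want_scores = false) {
  const arma::uword K = D.n_cols;
  const arma::uword nT = D.n_rows;
  const arma::uword N = eta.n_rows;
  const arma::uword R = eta.n_cols;
  const double sigma = par(K);
  const arma::vec beta = par.head(K);
  const arma::vec a = s % (D * beta);

  arma::mat logP(N, R, arma::fill::zeros);
  for (arma::uword r = 0; r < R; ++r) {
    const double* e = eta.colptr(r);
    double* lpcol = logP.colptr(r);
    for (arma::uword t = 0; t < nT; ++t) {
      const double x = a(t) + sigma * s(t) * e[resp(t)];
      const double lp =
          x > 0 ? -std::log1p(std::exp(-x)) : x - std::log1p(std::exp(x));
      lpcol[resp(t)] += lp;
    }
  }

  arma::vec ll(N);
  for (arma::uword n = 0; n < N; ++n) {
    const double m = logP.row(n).max();
    double acc = 0.0;
    for (arma::uword r = 0; r < R; ++r) acc += std::exp(logP(n, r) - m);
    ll(n) = m + std::log(acc / R);
  }
  const double total = arma::accu(ll);
  if (!want_grad && !want_scores) {
    return List::create(_["loglik"] = total);
  }

  arma::vec grad(K + 1, arma::fill::zeros);
  arma::mat scores;
  if (want_scores) scores.zeros(N, K + 1);
  arma::vec c(nT);
  for (arma::uword r = 0; r < R; ++r) {
    const double* e = eta.colptr(r);
    const double* lpcol = logP.colptr(r);
    double gsig = 0.0;
    for (arma::uword t = 0; t < nT; ++t) {
      const arma::uword n = resp(t);
      const double x = a(t) + sigma * s(t) * e[n];
      const double q = 1.0 / (1.0 + std::exp(x));  // plogis(-x)
      const double w = std::exp(lpcol[n] - ll(n)) / R;
      c(t) = w * q * s(t);
      gsig += c(t) * e[n];
    }
    grad.head(K) += D.t() * c;  // BLAS accumulation of the beta gradient
    grad(K) += gsig;
    if (want_scores) {
      for (arma::uword t = 0; t < nT; ++t) {
        const arma::uword n = resp(t);
        for (arma::uword k = 0; k < K; ++k) scores(n, k) += c(t) * D(t, k);
        scores(n, K) += c(t) * e[n];
      }
    }
  }
  if (want_scores) {
    return List::create(_["loglik"] = total, _["gradient"] = grad,
                        _["scores"] = scores);
  }
  return List::create(_["loglik"] = total, _["gradient"] = grad);
}
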