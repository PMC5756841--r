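#include <Rcpp.h>
using namespace Rcpp;

// Exact marginal log-likelihood of interval-censored daily Bernoulli
// survival with an absorbing failure state. Rows of X are exposure days
// (one per day per interval), interval_id maps each day-row to its
// interval (0-based), failed flags intervals ending in discovered failure.
// For an interval let P = prod_t S_t with logit(S_t) = x_t' beta; the
// contribution is log P if the nest survived the interval and log(1 - P)
// if it failed within it (the sum over all possible failure days).

// Rows may carry a weight = number of exposure days sharing that design
// row (an interval with nest-constant covariates collapses to one row).
// [[Rcpp::export]]
double intervals_loglik_cpp(const NumericMatrix& X,
                            const IntegerVector& interval_id,
                            const NumericVector& weight,
                            const LogicalVector& failed,
                            const NumericVector& beta) {
  const int n = X.nrow(), p = X.ncol(), m = failed.size();
  if (beta.size() != p) stop("beta length does not match design columns");
  std::vector<double> logp(m, 0.0);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * beta[j];
    if (!std::isfinite(eta)) stop("non-finite linear predictor");
    // log S = -log(1 + exp(-eta)), computed stably on both tails
    double ls = (eta > 0.0) ? -log1p(std::exp(-eta))
                            : eta - log1p(std::exp(eta));
    logp[interval_id[i]] += weight[i] * ls;
  }
  double ll = 0.0;
  for (int k = 0; k < m; ++k) {
    if (failed[k]) {
      double lp = logp[k];
      if (lp >= 0.0) return -std::numeric_limits<double>::infinity();
      ll += (lp > -M_LN2) ? std::log(-expm1(lp)) : log1p(-std::exp(lp));
    } else {
      ll += logp[k];
    }
  }
  return ll;
}
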