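#include <Rcpp.h>
using namespace Rcpp;

// Log-posterior of the daily nest-survival model: interval-marginal
// likelihood + independent Normal(0, prior_sd) priors on fixed
// coefficients; optional year random intercepts with Normal(0, sigma)
// prior and half-Normal(0, 5) hyperprior on sigma (sampled as log sigma,
// with Jacobian).
static double log_post_nest(const NumericMatrix& X,
                            const IntegerVector& interval_id,
                            const NumericVector& weight,
                            const LogicalVector& failed,
                            const std::vector<double>& theta,
                            int n_fixed, int n_ranef, double prior_sd) {
  const int n = X.nrow(), p = X.ncol(), m = failed.size();
  std::vector<double> logp(m, 0.0);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int j = 0; j < p; ++j) eta += X(i, j) * theta[j];
    if (!std::isfinite(eta)) return R_NegInf;
    double ls = (eta > 0.0) ? -log1p(std::exp(-eta))
                            : eta - log1p(std::exp(eta));
    logp[interval_id[i]] += weight[i] * ls;
  }
  double ll = 0.0;
  for (int k = 0; k < m; ++k) {
    if (failed[k]) {
      double lp = logp[k];
      if (lp >= 0.0) return R_NegInf;
      ll += (lp > -M_LN2) ? std::log(-expm1(lp)) : log1p(-std::exp(lp));
    } else {
      ll += logp[k];
    }
  }
  for (int j = 0; j < n_fixed; ++j)
    ll += R::dnorm(theta[j], 0.0, prior_sd, 1);
  if (n_ranef > 0) {
    double log_sig = theta[p];
    double sig = std::exp(log_sig);
    for (int j = n_fixed; j < p; ++j)
      ll += R::dnorm(theta[j], 0.0, sig, 1);
    ll += R::dnorm(sig, 0.0, 5.0, 1) + M_LN2 + log_sig;
  }
  return std::isfinite(ll) ? ll : R_NegInf;
}

// in-place lower Cholesky; returns false if not positive definite
static bool cholesky(std::vector<double>& a, int p) {
  for (int j = 0; j < p; ++j) {
    double d = a[j * p + j];
    for (int k = 0; k < j; ++k) d -= a[j * p + k] * a[j * p + k];
    if (d <= 0.0) return false;
    a[j * p + j] = std::sqrt(d);
    for (int i = j + 1; i < p; ++i) {
      double s = a[i * p + j];
      for (int k = 0; k < j; ++k) s -= a[i * p + k] * a[j * p + k];
      a[i * p + j] = s / a[j * p + j];
    }
    for (int k = j + 1; k < p; ++k) a[j * p + k] = 0.0;
  }
  return true;
}

// One adaptive random-walk Metropolis chain for the nest-survival
// posterior. Mirrors the reference R sampler (run_mcmc): Gaussian
// proposal scale tuned by Robbins-Monro toward 0.3 acceptance during
// warmup, proposal covariance refreshed from the second half of the
// warmup draws, post-warmup draws returned. Uses R's RNG, so
// set.seed() upstream makes the chain deterministic.
// [[Rcpp::export]]
List mcmc_nest_chain_cpp(const NumericMatrix& X,
                         const IntegerVector& interval_id,
                         const NumericVector& weight,
                         const LogicalVector& failed,
                         const NumericVector& init,
                         int n_fixed, int n_ranef, double prior_sd,
                         int iter, int warmup) {
  const int p = init.size();
  std::vector<double> theta(init.begin(), init.end());
  double lp = log_post_nest(X, interval_id, weight, failed, theta,
                            n_fixed, n_ranef, prior_sd);
  if (!std::isfinite(lp))
    stop("non-finite log posterior at initial value");

  double log_scale = std::log(2.38 / std::sqrt((double)p));
  std::vector<double> L(p * p, 0.0);
  for (int j = 0; j < p; ++j) L[j * p + j] = 1.0;
  std::vector<double> warm((size_t)warmup * p);
  NumericMatrix draws(iter, p);
  std::vector<double> prop(p), z(p);
  int n_accept = 0;

  for (int i = 1; i <= warmup + iter; ++i) {
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    double sc = std::exp(log_scale);
    for (int j = 0; j < p; ++j) {
      double step = 0.0;
      for (int k = 0; k <= j; ++k) step += L[j * p + k] * z[k];
      prop[j] = theta[j] + sc * step;
    }
    double lpp = log_post_nest(X, interval_id, weight, failed, prop,
                               n_fixed, n_ranef, prior_sd);
    double a = std::isfinite(lpp) ? std::min(1.0, std::exp(lpp - lp))
                                  : 0.0;
    bool accepted = unif_rand() < a;
    if (accepted) {
      theta = prop;
      lp = lpp;
    }
    if (i <= warmup) {
      log_scale += (a - 0.3) / std::pow((double)i, 0.6);
      for (int j = 0; j < p; ++j) warm[(size_t)(i - 1) * p + j] = theta[j];
      if (i >= 200 && i % 100 == 0) {
        int lo = i / 2 - 1, n_win = i - lo;  // rows lo..i-1 (0-based)
        std::vector<double> mu(p, 0.0);
        for (int r = lo; r < i; ++r)
          for (int j = 0; j < p; ++j) mu[j] += warm[(size_t)r * p + j];
        for (int j = 0; j < p; ++j) mu[j] /= n_win;
        std::vector<double> cv(p * p, 0.0);
        for (int r = lo; r < i; ++r)
          for (int j = 0; j < p; ++j) {
            double dj = warm[(size_t)r * p + j] - mu[j];
            for (int k = 0; k <= j; ++k)
              cv[j * p + k] += dj * (warm[(size_t)r * p + k] - mu[k]);
          }
        for (int j = 0; j < p; ++j)
          for (int k = 0; k <= j; ++k) {
            cv[j * p + k] /= (n_win - 1);
            cv[k * p + j] = cv[j * p + k];
          }
        for (int j = 0; j < p; ++j)
          cv[j * p + j] += 1e-8 + 1e-6 * cv[j * p + j];
        std::vector<double> Lc(cv);
        if (cholesky(Lc, p)) L = Lc;
      }
    } else {
      for (int j = 0; j < p; ++j) draws(i - warmup - 1, j) = theta[j];
      if (accepted) ++n_accept;
    }
  }
  return List::create(_["draws"] = draws,
                      _["acceptance"] = (double)n_accept / iter);
}
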