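#' MCMC settings for [fit_survival()]
#'
#' Defaults reproduce a conventional field configuration: 3 chains with
#' 30,000 kept iterations each after 20,000 warmup (90,000 pooled draws).
#' Simulation experiments and tests use far shorter chains via this
#' control object.
#'
#' @param chains number of independent chains.
#' @param iter kept iterations per chain (after warmup).
#' @param warmup adaptation iterations per chain, discarded.
#' @param seed master seed; per-chain seeds are derived from it.
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 3, iter = 30000, warmup = 20000,
                         seed = 1) {
  stopifnot(chains >= 1, iter >= 1, warmup >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Adaptive random-walk Metropolis sampler
#'
#' Generic multivariate random-walk Metropolis with warmup adaptation:
#' the proposal is Gaussian with covariance `scale^2 * Sigma`, where
#' `scale` is tuned by Robbins-Monro toward an acceptance rate of 0.3
#' (inside the 0.2-0.5 band appropriate for random-walk proposals) and
#' `Sigma` is refreshed from the accumulating warmup draws. Exposed so
#' sampler correctness can be checked directly against known targets.
#'
#' @param log_post function of the parameter vector returning the
#'   unnormalized log posterior density.
#' @param init numeric initial parameter vector.
#' @param control an [mcmc_control()].
#' @return List with `draws` (pooled post-warmup matrix, `iter * chains`
#'   rows), `chain` (chain index per row), and `acceptance` (realized
#'   post-warmup acceptance rate per chain).
#' @export
run_mcmc <- function(log_post, init, control = mcmc_control()) {
  p <- length(init)
  chain_seeds <- withr::with_seed(control$seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             control$chains))
  draws <- vector("list", control$chains)
  acc <- numeric(control$chains)
  for (ch in seq_len(control$chains)) {
    res <- run_chain(log_post, init, control$iter, control$warmup,
                     chain_seeds[ch])
    draws[[ch]] <- res$draws
    acc[ch] <- res$acceptance
  }
  list(draws = do.call(rbind, draws),
       chain = rep(seq_len(control$chains), each = control$iter),
       acceptance = acc)
}

run_chain <- function(log_post, init, iter, warmup, seed) {
  withr::with_seed(seed, {
    p <- length(init)
    theta <- as.numeric(init)
    lp <- log_post(theta)
    if (!is.finite(lp))
      stop("non-finite log posterior at initial value", call. = FALSE)
    log_scale <- log(2.38 / sqrt(p))
    L <- diag(1, p)
    warm <- matrix(NA_real_, warmup, p)
    draws <- matrix(NA_real_, iter, p)
    n_accept <- 0L
    for (i in seq_len(warmup + iter)) {
      prop <- theta + exp(log_scale) * drop(L %*% stats::rnorm(p))
      lpp <- log_post(prop)
      a <- if (is.finite(lpp)) min(1, exp(lpp - lp)) else 0
      accepted <- stats::runif(1) < a
      if (accepted) {
        theta <- prop
        lp <- lpp
      }
      if (i <= warmup) {
        log_scale <- log_scale + (a - 0.3) / i^0.6
        warm[i, ] <- theta
        if (i >= 200L && i %% 100L == 0L) {
          cv <- stats::cov(warm[(i %/% 2):i, , drop = FALSE])
          cv <- cv + diag(1e-8 + 1e-6 * diag(cv), p)
          Lt <- tryCatch(t(chol(cv)), error = function(e) NULL)
          if (!is.null(Lt)) L <- Lt
        }
      } else {
        draws[i - warmup, ] <- theta
        n_accept <- n_accept + accepted
      }
    }
    list(draws = draws, acceptance = n_accept / iter)
  })
}

#' Fit the Bayesian daily nest-survival model
#'
#' Samples the posterior of the logit-linear daily survival model defined
#' by `spec` using the exact interval-marginal likelihood (see
#' [interval_loglik()]) and a compiled implementation of the adaptive
#' Metropolis scheme of [run_mcmc()] (the R sampler serves as the
#' reference implementation in the test suite).
#' Coefficients get independent Normal(0, `spec$prior_sd`) priors; when a
#' year random intercept is requested, the year effects get
#' Normal(0, `sigma_year`) with a half-Normal(0, 5) hyperprior on
#' `sigma_year`, sampled on the log scale.
#'
#' @param study a `"nest_study"`.
#' @param spec a [survival_model_spec()].
#' @param control an [mcmc_control()].
#' @param data optional nests table replacing `study$nests` (e.g. with a
#'   `grass_height_corrected` column joined on).
#' @return An object of class `"survival_posterior"`: pooled post-warmup
#'   `draws`, per-parameter `summary` (mean, sd, quantiles 2.5/50/97.5%,
#'   split-chain R-hat, effective sample size), `converged` flag (all
#'   R-hat <= 1.1; a non-converged fit is returned flagged, not
#'   discarded), acceptance rates, and the covariate centering/range
#'   metadata needed by [success_curve()].
#' @export
fit_survival <- function(study, spec = survival_model_spec(),
                         control = mcmc_control(), data = NULL) {
  ints <- build_intervals(study, spec, data)
  pX <- ncol(ints$X)
  has_hyper <- ints$n_ranef > 0
  prior_sd <- spec$prior_sd

  # crude initial daily survival from failures per exposure day
  n_fail <- sum(ints$failed)
  s0 <- min(0.999, max(0.5, 1 - n_fail / ints$exposure_days))
  init <- c(stats::qlogis(s0), rep(0, pX - 1L), if (has_hyper) 0)

  chain_seeds <- withr::with_seed(control$seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             control$chains))
  chain_res <- lapply(seq_len(control$chains), function(ch) {
    withr::with_seed(chain_seeds[ch],
      mcmc_nest_chain_cpp(ints$X_s, ints$interval_s, ints$weight_s,
                          ints$failed, init,
                          ints$n_fixed, ints$n_ranef, prior_sd,
                          control$iter, control$warmup))
  })
  res <- list(
    draws = do.call(rbind, lapply(chain_res, `[[`, "draws")),
    chain = rep(seq_len(control$chains), each = control$iter),
    acceptance = vapply(chain_res, `[[`, numeric(1), "acceptance")
  )
  par_names <- c(colnames(ints$X), if (has_hyper) "log_sigma_year")
  colnames(res$draws) <- par_names

  summ <- summarize_draws(res$draws, res$chain, control$chains,
                          control$iter)
  structure(list(
    draws = res$draws, chain = res$chain,
    chains = control$chains, iter = control$iter, warmup = control$warmup,
    acceptance = res$acceptance,
    summary = summ,
    converged = all(summ$rhat <= 1.1, na.rm = TRUE),
    spec = spec,
    centers = ints$centers, ranges = ints$ranges,
    age_center = ints$age_center, col_means = ints$col_means,
    n_fixed = ints$n_fixed,
    incubation_days = if (!is.null(study$config))
      study$config$incubation_days else 27L,
    n_intervals = nrow(ints$intervals),
    exposure_days = ints$exposure_days
  ), class = "survival_posterior")
}

summarize_draws <- function(draws, chain, n_chains, iter) {
  out <- lapply(seq_len(ncol(draws)), function(j) {
    arr <- matrix(draws[, j], nrow = iter, ncol = n_chains)
    q <- stats::quantile(draws[, j], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = colnames(draws)[j],
               mean = mean(draws[, j]), sd = stats::sd(draws[, j]),
               q2.5 = q[1], q50 = q[2], q97.5 = q[3],
               rhat = split_rhat(arr), ess = ess_mean(arr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# split-chain potential scale reduction factor
split_rhat <- function(arr) {
  n <- nrow(arr)
  half <- n %/% 2
  sp <- cbind(arr[seq_len(half), , drop = FALSE],
              arr[(n - half + 1):n, , drop = FALSE])
  w <- mean(apply(sp, 2, stats::var))
  b <- half * stats::var(colMeans(sp))
  if (w <= 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size from chain-averaged autocorrelations with
# Geyer's initial-positive-sequence truncation
ess_mean <- function(arr) {
  n <- nrow(arr); m <- ncol(arr)
  max_lag <- min(n - 1L, 1000L)
  acov <- vapply(seq_len(m), function(c)
    stats::acf(arr[, c], lag.max = max_lag, plot = FALSE,
               type = "covariance", demean = TRUE)$acf[, 1, 1],
    numeric(max_lag + 1L))
  w <- mean(acov[1, ]) * n / (n - 1)
  b <- if (m > 1) stats::var(colMeans(arr)) else 0
  var_plus <- w * (n - 1) / n + b
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (w - rowMeans(acov)[-1]) / var_plus
  # sum consecutive pairs while positive
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  min(m * n, m * n / tau)
}

#' @export
print.survival_posterior <- function(x, digits = 3, ...) {
  cat(sprintf("<survival_posterior> %d chains x %d kept (%d warmup), %s\n",
              x$chains, x$iter, x$warmup,
              if (x$converged) "converged (all R-hat <= 1.1)"
              else "NOT converged (some R-hat > 1.1)"))
  cat(sprintf("  %d intervals, %d exposure days; acceptance %s\n",
              x$n_intervals, x$exposure_days,
              paste(sprintf("%.2f", x$acceptance), collapse = "/")))
  print(format(x$summary, digits = digits), ...)
  invisible(x)
}

#' Posterior nest-success curve over grass height
#'
#' For each posterior draw and each grid value of the grass-height
#' covariate, computes nest success as the product of daily survival over
#' the incubation period (default: the study's incubation length, 27
#' days), holding all other covariates at their mean (and year random
#' effects at 0, i.e. a typical year). Time-varying age terms follow the
#' within-incubation age trajectory. Reports the pointwise posterior mean
#' and 95% credible band.
#'
#' @param posterior a `"survival_posterior"` from [fit_survival()].
#' @param grass numeric grid of grass heights (cm); default is 50 points
#'   over the observed range of the covariate. Values outside the observed
#'   range trigger a warning (extrapolation), not an error.
#' @param covariate name of the grass-height covariate; defaults to the
#'   first covariate in the model spec.
#' @param days number of days of daily survival to multiply; defaults to
#'   the incubation period.
#' @return Data frame of class `"success_curve"`: `grass`, `mean`, `lo95`,
#'   `hi95`.
#' @export
success_curve <- function(posterior, grass = NULL, covariate = NULL,
                          days = NULL) {
  stopifnot(inherits(posterior, "survival_posterior"))
  if (is.null(covariate)) covariate <- posterior$spec$covariates[1]
  if (!covariate %in% names(posterior$centers))
    stop("`", covariate, "` is not a numeric covariate of the model",
         call. = FALSE)
  rng <- posterior$ranges[[covariate]]
  if (is.null(grass)) grass <- seq(rng[1], rng[2], length.out = 50)
  if (any(grass < rng[1] | grass > rng[2]))
    warning("grass grid extends outside the observed covariate range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (is.null(days)) days <- posterior$incubation_days

  draws <- posterior$draws
  fixed_names <- names(posterior$col_means)
  # column means of the nest-level design: intercept 1, centered numeric
  # covariates ~0, factor dummies at their observed proportions
  xbase <- posterior$col_means
  spec <- posterior$spec

  mean_lo_hi <- vapply(grass, function(g) {
    x <- xbase
    x[covariate] <- g - posterior$centers[covariate]
    eta0 <- drop(draws[, fixed_names, drop = FALSE] %*% x)
    if (spec$age) {
      ages <- seq_len(days) - posterior$age_center
      log_s <- numeric(nrow(draws))
      for (a in ages) {
        eta <- eta0 + draws[, "age"] * a
        if (spec$age_quadratic) eta <- eta + draws[, "age2"] * a^2
        log_s <- log_s + stats::plogis(eta, log.p = TRUE)
      }
      succ <- exp(log_s)
    } else {
      succ <- stats::plogis(eta0)^days
    }
    c(mean(succ), stats::quantile(succ, c(0.025, 0.975), names = FALSE))
  }, numeric(3))

  out <- data.frame(grass = grass, mean = mean_lo_hi[1, ],
                    lo95 = mean_lo_hi[2, ], hi95 = mean_lo_hi[3, ])
  class(out) <- c("success_curve", "data.frame")
  out
}
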