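#' Fit a pooled grass-height phenology mixed model
#'
#' Models nest-level grass height (`gh`) as a linear function of the day
#' of measurement with study-area x year (`stratum`) random effects:
#' either random intercepts only, `gh ~ day + (1 | stratum)`, or random
#' intercepts and slopes with unstructured covariance,
#' `gh ~ day + (day | stratum)`. Optionally adds a fixed effect of nest
#' fate — the alternative hypothesis that grass is taller at successful
#' nests after accounting for phenology. `day` is centered by subtracting
#' the median measurement day before fitting (slope and log-likelihood
#' are invariant to the centering).
#'
#' Estimation is by [lme4::lmer()]. Variance components estimated at the
#' boundary (a singular fit) are returned with `singular = TRUE`, not
#' suppressed.
#'
#' @param data data frame with columns `gh` (cm), `day` (ordinal day of
#'   measurement), `stratum` (study-area x year id), and — if
#'   `fate_effect` — `fate` coded `"HATCHED"`/`"FAILED"` (or 1/0).
#' @param random `"intercept"` or `"slope"` (random intercepts and
#'   slopes).
#' @param fate_effect include the fixed nest-fate effect.
#' @param method `"REML"` (for comparing random structures) or `"ML"`
#'   (required for the likelihood-ratio test on the fixed fate effect).
#' @return Object of class `"lmm_fit"`: the underlying `lmerMod` plus
#'   `logLik`, `k` (parameters counted as fixed effects +
#'   variance/covariance components + residual), `n_obs`, fixed-effect
#'   table, variance components, `singular` flag, and the day-centering
#'   constant.
#' @export
fit_lmm <- function(data, random = c("intercept", "slope"),
                    fate_effect = FALSE, method = c("REML", "ML")) {
  random <- match.arg(random)
  method <- match.arg(method)
  req <- c("gh", "day", "stratum")
  if (fate_effect) req <- c(req, "fate")
  if (!all(req %in% names(data)))
    stop("`data` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (length(unique(data$stratum)) < 2)
    stop("at least 2 strata are required for a mixed model", call. = FALSE)
  d <- data
  day_center <- stats::median(d$day)
  d$day_c <- d$day - day_center
  if (fate_effect && !is.numeric(d$fate))
    d$fate <- as.integer(d$fate == "HATCHED")
  re <- if (random == "slope") "(day_c | stratum)" else "(1 | stratum)"
  fe <- if (fate_effect) "gh ~ day_c + fate + " else "gh ~ day_c + "
  form <- stats::as.formula(paste0(fe, re))
  # best-of-two optimizers: near-singular random-slope fits can leave one
  # optimizer in a local optimum, which would break LRT nesting
  fit_with <- function(optimizer) {
    suppressMessages(suppressWarnings(tryCatch(
      lme4::lmer(form, data = d, REML = (method == "REML"),
                 control = lme4::lmerControl(
                   optimizer = optimizer,
                   optCtrl = if (optimizer == "bobyqa")
                     list(maxfun = 100000) else list(),
                   check.conv.singular = "ignore")),
      error = function(e) NULL)))
  }
  fit <- fit_with("bobyqa")
  fit2 <- fit_with("nloptwrap")
  if (is.null(fit) ||
      (!is.null(fit2) && stats::logLik(fit2) > stats::logLik(fit) + 1e-8))
    fit <- fit2
  if (is.null(fit))
    stop("mixed-model fit failed to converge under both optimizers",
         call. = FALSE)
  ll <- stats::logLik(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    model = fit,
    formula = form,
    random = random,
    fate_effect = fate_effect,
    method = method,
    logLik = as.numeric(ll),
    k = attr(ll, "df"),
    n_obs = stats::nobs(fit),
    fixed = lme4::fixef(fit),
    varcorr = vc,
    singular = lme4::isSingular(fit, tol = 1e-4),
    day_center = day_center
  )
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, random %s%s, logLik %.3f (k = %d, n = %d)%s\n",
              x$method, x$random,
              if (x$fate_effect) " + fate effect" else "",
              x$logLik, x$k, x$n_obs,
              if (x$singular) " [boundary/singular fit]" else ""))
  print(x$fixed)
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`, with `k` the number
#' of estimated parameters (fixed effects plus variance/covariance
#' components plus the residual variance for a mixed model) and `n` the
#' number of observations.
#'
#' @param object an `"lmm_fit"`, or a log-likelihood value.
#' @param k,n parameter count and sample size (only for the default
#'   method).
#' @param ... unused.
#' @return The AICc value.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.default <- function(object, k, n, ...) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 must be positive", call. = FALSE)
  -2 * object + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aicc.lmm_fit <- function(object, ...) {
  aicc.default(object$logLik, object$k, object$n_obs)
}

#' Likelihood-ratio test for the nest-fate effect
#'
#' Compares two nested maximum-likelihood mixed-model fits: the null
#' phenology model and the alternative adding a fixed nest-fate effect.
#' The statistic `2 * (logLik_alt - logLik_null)` is referred to the
#' upper tail of a chi-squared distribution with 1 degree of freedom.
#'
#' @param null_fit,alt_fit `"lmm_fit"` objects fit with `method = "ML"`;
#'   `alt_fit` must add exactly the fate fixed effect to `null_fit`.
#' @return Object of class `"nestpheno_test"`: `statistic`, `df`,
#'   `p_value`, `alternative`.
#' @export
lrt_fate <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "lmm_fit"), inherits(alt_fit, "lmm_fit"))
  if (null_fit$method != "ML" || alt_fit$method != "ML")
    stop("likelihood-ratio test requires ML fits (method = \"ML\")",
         call. = FALSE)
  if (null_fit$fate_effect || !alt_fit$fate_effect)
    stop("`alt_fit` must add the fate effect to a null without it",
         call. = FALSE)
  if (null_fit$random != alt_fit$random)
    stop("fits must share the same random-effect structure", call. = FALSE)
  stat <- 2 * (alt_fit$logLik - null_fit$logLik)
  if (stat < -1e-6)
    stop("alternative log-likelihood below null: optimizer failure or ",
         "non-nested fits (difference ", signif(stat, 3), ")",
         call. = FALSE)
  stat <- max(0, stat)
  structure(list(
    statistic = stat, df = 1L,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    alternative = "grass taller at successful nests after phenology",
    method = "likelihood-ratio test (chi-squared, 1 df)"
  ), class = "nestpheno_test")
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether grass heights at hatched nests are stochastically larger
#' than at failed nests. The statistic is
#' `D+ = sup_x [ECDF_failed(x) - ECDF_hatched(x)]`, evaluated at all
#' pooled jump points (so ties need no randomization). The p-value is the
#' exact label-permutation probability `P(D+ >= observed)` over all
#' `choose(m + n, m)` assignments when `m + n <= exact_limit`, and the
#' one-sided asymptotic tail `exp(-2 D+^2 m n / (m + n))` otherwise.
#'
#' @param heights_hatched,heights_failed numeric vectors of grass heights
#'   (cm) at hatched and failed nests.
#' @param exact_limit largest pooled sample size for which the exact
#'   enumeration is used (default 20).
#' @return Object of class `"nestpheno_test"`: `statistic` (D+), sample
#'   sizes, `p_value`, `alternative`, and whether the exact enumeration
#'   was used.
#' @export
ks_one_sided <- function(heights_hatched, heights_failed,
                         exact_limit = 20) {
  h <- as.numeric(heights_hatched)
  f <- as.numeric(heights_failed)
  if (!length(h) || !length(f))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(h) || anyNA(f)) stop("samples must not contain NA",
                                 call. = FALSE)
  d_obs <- ks_dplus(f, h)
  n_h <- length(h); n_f <- length(f); n_tot <- n_h + n_f
  exact <- n_tot <= exact_limit
  if (exact) {
    pool <- c(f, h)
    idx <- utils::combn(n_tot, n_f)
    stats_perm <- apply(idx, 2, function(ii)
      ks_dplus(pool[ii], pool[-ii]))
    p <- mean(stats_perm >= d_obs - 1e-12)
  } else {
    p <- min(1, exp(-2 * d_obs^2 * n_f * n_h / n_tot))
  }
  structure(list(
    statistic = d_obs, n_hatched = n_h, n_failed = n_f,
    p_value = p, exact = exact,
    alternative = "hatched-nest heights stochastically larger",
    method = "one-sided two-sample Kolmogorov-Smirnov test"
  ), class = "nestpheno_test")
}

# D+ = sup over pooled jump points of ECDF(f) - ECDF(h)
ks_dplus <- function(f, h) {
  x <- sort(unique(c(f, h)))
  ff <- findInterval(x, sort(f)) / length(f)
  fh <- findInterval(x, sort(h)) / length(h)
  max(ff - fh)
}

#' @export
print.nestpheno_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  if (!is.null(x$df)) {
    cat(sprintf("  statistic = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  D+ = %.4g (n hatched = %d, failed = %d), p = %.4g%s\n",
                x$statistic, x$n_hatched, x$n_failed, x$p_value,
                if (isTRUE(x$exact)) " [exact]" else ""))
  }
  cat("  alternative:", x$alternative, "\n")
  invisible(x)
}

#' Assemble the pooled-analysis data frame
#'
#' Joins corrected heights to nest records in the `gh`/`day`/`fate`/
#' `stratum` layout expected by [fit_lmm()] and [ks_one_sided()].
#'
#' With `use = "measured"` (the default, and the layout for the pooled
#' mixed model), `gh` is the measured height and `day` the day of
#' measurement: phenology is accounted for by the DAY term of the model.
#' With `use = "corrected"`, `gh` is the height standardized to hatch
#' date and `day` is the hatch day — a corrected height is a measurement
#' referenced to hatch date, so pairing it with the original measurement
#' day would re-introduce a spurious fate-dependent offset (failed nests
#' are corrected forward to a later date than they were measured).
#'
#' @param cd a `"corrected_heights"` data frame from [correct_heights()].
#' @param use `"measured"` (default) or `"corrected"`.
#' @return Data frame with columns `gh`, `day`, `fate`, `stratum`.
#' @export
pooled_data <- function(cd, use = c("measured", "corrected")) {
  use <- match.arg(use)
  stopifnot(is.data.frame(cd))
  if (is.null(cd$fate))
    stop("corrected-heights table carries no `fate` column", call. = FALSE)
  data.frame(
    gh = if (use == "corrected") cd$grass_height_corrected
         else cd$grass_height_mean,
    day = if (use == "corrected") cd$hatch_day else cd$measurement_day,
    fate = cd$fate,
    stratum = paste(cd$site_id, cd$year, sep = ":"),
    stringsAsFactors = FALSE
  )
}
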