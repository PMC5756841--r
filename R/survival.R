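#' Specify a daily nest-survival model
#'
#' Describes the logit-linear model for daily nest survival,
#' `logit(S[i,t]) = beta0 + x[i,t]' beta`: which nest-level covariate
#' columns enter (numeric covariates are centered so coefficients stay on
#' their per-unit scale; character/factor columns become treatment-coded
#' indicators), whether nest age and its quadratic enter as time-varying
#' terms, and whether year enters as a random intercept. All coefficients
#' get independent vague Normal(0, `prior_sd`) priors; the year random
#' effects get Normal(0, `sigma_year`) with a half-Normal(0, 5) hyperprior
#' on `sigma_year`.
#'
#' @param covariates character vector of nest-level covariate column names
#'   (e.g. `"grass_height_mean"` or `"grass_height_corrected"`).
#' @param age include nest age (days since initiation, centered at the
#'   mean exposure-day age) as a daily covariate.
#' @param age_quadratic also include the square of centered age (implies
#'   `age`).
#' @param year_random include a random intercept per year.
#' @param prior_sd SD of the normal prior on all coefficients.
#' @param center_covariates center numeric covariates at their nest-level
#'   mean before fitting (default; keeps the grass coefficient per-cm).
#' @return An object of class `"survival_model_spec"`.
#' @export
survival_model_spec <- function(covariates = "grass_height_mean",
                                age = FALSE,
                                age_quadratic = FALSE,
                                year_random = FALSE,
                                prior_sd = 1000,
                                center_covariates = TRUE) {
  if (age_quadratic) age <- TRUE
  if (anyDuplicated(covariates))
    stop("covariate names must be unique", call. = FALSE)
  if (!is.numeric(prior_sd) || prior_sd <= 0)
    stop("`prior_sd` must be > 0", call. = FALSE)
  structure(list(covariates = covariates, age = age,
                 age_quadratic = age_quadratic, year_random = year_random,
                 prior_sd = prior_sd, center_covariates = center_covariates),
            class = "survival_model_spec")
}

#' Build encounter intervals and the day-level design matrix
#'
#' Converts each nest's encounter history into intervals between
#' consecutive visits. An interval from visit day `a` to visit day `b`
#' covers exposure days `a+1, ..., b`; its outcome is `FAILED_WITHIN` if
#' the nest was found failed at day `b`, else `SURVIVED`. Because failure
#' is absorbing, the interval likelihood marginalizes the unknown failure
#' day exactly (see [interval_loglik()]).
#'
#' @param study a `"nest_study"` (visits are taken from it).
#' @param spec a [survival_model_spec()].
#' @param data optional replacement for `study$nests` carrying the
#'   covariate columns (e.g. nests joined to corrected heights).
#' @return An object of class `"nest_intervals"`: the interval table, the
#'   day-level design matrix `X`, the per-day interval index, the
#'   per-interval outcome, covariate centering constants and observed
#'   ranges, and parameter names.
#' @export
build_intervals <- function(study, spec = survival_model_spec(),
                            data = NULL) {
  stopifnot(inherits(study, "nest_study"),
            inherits(spec, "survival_model_spec"))
  nests <- if (is.null(data)) study$nests else data
  visits <- study$visits
  missing_cov <- setdiff(spec$covariates, names(nests))
  if (length(missing_cov))
    stop("covariate column(s) not found: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)

  vis_by_nest <- split(visits[, c("day", "state")], visits$nest_id)
  ord <- match(nests$nest_id, names(vis_by_nest))
  if (anyNA(ord))
    stop("nests without visits: ",
         paste(nests$nest_id[is.na(ord)], collapse = ", "), call. = FALSE)

  ivl_nest <- integer(0); ivl_start <- integer(0); ivl_end <- integer(0)
  ivl_failed <- logical(0)
  for (i in seq_len(nrow(nests))) {
    v <- vis_by_nest[[ord[i]]]
    if (is.unsorted(v$day, strictly = TRUE))
      stop("non-monotone visit days for nest ", nests$nest_id[i],
           call. = FALSE)
    fail_idx <- which(v$state == "FAILED")
    if (length(fail_idx) > 1 ||
        (length(fail_idx) == 1 && fail_idx != nrow(v)))
      stop("failure must be absorbing and final for nest ",
           nests$nest_id[i], call. = FALSE)
    if (nrow(v) < 2) next
    k <- nrow(v) - 1L
    ivl_nest <- c(ivl_nest, rep(i, k))
    ivl_start <- c(ivl_start, v$day[-nrow(v)])
    ivl_end <- c(ivl_end, v$day[-1])
    ivl_failed <- c(ivl_failed, v$state[-1] == "FAILED")
  }
  if (!length(ivl_nest)) stop("no usable encounter intervals", call. = FALSE)

  n_days <- ivl_end - ivl_start
  day_interval <- rep(seq_along(ivl_nest), n_days)
  day_nest <- ivl_nest[day_interval]
  day <- unlist(lapply(seq_along(ivl_nest),
                       function(k) (ivl_start[k] + 1L):ivl_end[k]))

  # nest-level fixed-effects design (intercept + covariates)
  centers <- numeric(0); ranges <- list()
  Z <- matrix(1, nrow(nests), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in spec$covariates) {
    col <- nests[[cv]]
    if (is.numeric(col)) {
      ctr <- if (spec$center_covariates) mean(col) else 0
      centers[cv] <- ctr
      ranges[[cv]] <- range(col)
      Z <- cbind(Z, matrix(col - ctr, ncol = 1,
                           dimnames = list(NULL, cv)))
    } else {
      f <- factor(col)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      Z <- cbind(Z, mm)
    }
  }

  X <- Z[day_nest, , drop = FALSE]
  age_center <- NA_real_
  if (spec$age) {
    age <- day - nests$initiation_day[day_nest]
    age_center <- mean(age)
    X <- cbind(X, age = age - age_center)
    if (spec$age_quadratic) X <- cbind(X, age2 = (age - age_center)^2)
  }
  year_levels <- NULL
  if (spec$year_random) {
    yf <- factor(nests$year)
    year_levels <- levels(yf)
    U <- stats::model.matrix(~ yf - 1)[day_nest, , drop = FALSE]
    colnames(U) <- paste0("year_", year_levels)
    X <- cbind(X, U)
  }
  n_ranef <- if (spec$year_random) length(year_levels) else 0L

  # sampler design: with no time-varying terms, every exposure day in an
  # interval shares one design row, so collapse to one weighted row per
  # interval; with age terms keep the day-level rows (weight 1)
  if (spec$age) {
    X_s <- X
    interval_s <- day_interval - 1L
    weight_s <- rep(1, nrow(X))
  } else {
    first_rows <- match(seq_along(ivl_nest), day_interval)
    X_s <- X[first_rows, , drop = FALSE]
    interval_s <- seq_along(ivl_nest) - 1L
    weight_s <- as.numeric(n_days)
  }

  structure(list(
    intervals = data.frame(
      nest_id = nests$nest_id[ivl_nest],
      start_day = ivl_start, end_day = ivl_end,
      outcome = ifelse(ivl_failed, "FAILED_WITHIN", "SURVIVED"),
      stringsAsFactors = FALSE
    ),
    X = X,
    day_interval = day_interval - 1L,  # 0-based for the C++ kernel
    X_s = X_s, interval_s = interval_s, weight_s = weight_s,
    failed = ivl_failed,
    n_fixed = ncol(X) - n_ranef,
    n_ranef = n_ranef,
    year_levels = year_levels,
    centers = centers,
    ranges = ranges,
    age_center = age_center,
    col_means = colMeans(Z),
    exposure_days = length(day_interval),
    spec = spec
  ), class = "nest_intervals")
}

#' Exact log-likelihood of one encounter interval
#'
#' For an interval whose exposure days have design rows `X` (one row per
#' day) under coefficients `beta`, the survival probability through the
#' interval is `P = prod(plogis(X %*% beta))`. Returns `log(P)` for a
#' survived interval and `log(1 - P)` for an interval in which the nest
#' was found failed — the exact marginal over the unobserved failure day,
#' since failure is absorbing.
#'
#' @param X numeric matrix, one row per exposure day in the interval.
#' @param beta coefficient vector, length `ncol(X)`.
#' @param outcome `"SURVIVED"` or `"FAILED_WITHIN"`.
#' @return The interval log-likelihood (a single number).
#' @examples
#' X <- matrix(rep(stats::qlogis(0.9), 3), ncol = 1)  # 3 days at S = 0.9
#' interval_loglik(X, 1, "FAILED_WITHIN")             # log(1 - 0.9^3)
#' @export
interval_loglik <- function(X, beta, outcome = c("SURVIVED",
                                                 "FAILED_WITHIN")) {
  outcome <- match.arg(outcome)
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor", call. = FALSE)
  lp <- sum(stats::plogis(eta, log.p = TRUE))
  if (outcome == "SURVIVED") return(lp)
  if (lp > -log(2)) log(-expm1(lp)) else log1p(-exp(lp))
}

#' Total dataset log-likelihood over all intervals
#'
#' @param ints a `"nest_intervals"` object from [build_intervals()].
#' @param beta coefficient vector matching `ncol(ints$X)`.
#' @return The summed interval log-likelihood.
#' @export
study_loglik <- function(ints, beta) {
  stopifnot(inherits(ints, "nest_intervals"))
  intervals_loglik_cpp(ints$X_s, ints$interval_s, ints$weight_s,
                       ints$failed, as.numeric(beta))
}
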