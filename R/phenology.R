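#' Estimate within-season grass growth per study-area x year stratum
#'
#' For each stratum (site x year), fits an ordinary least-squares
#' regression of nest-level mean measured grass height on the day of
#' measurement. The slope is the stratum's within-season growth rate
#' (cm/day) used by [correct_heights()] to standardize measurements to
#' hatch date. The day covariate is centered at the stratum median
#' measurement day for numerical conditioning; the slope is invariant to
#' centering and the reported intercept is the fitted height at the
#' centering day.
#'
#' @param study a `"nest_study"`, or a data frame with columns `site_id`,
#'   `year`, `measurement_day`, `grass_height_mean`.
#' @param min_n minimum nests per stratum for a fit (default 3); smaller
#'   strata raise an error naming them rather than silently pooling.
#' @return A data frame of class `"phenology_fits"`: one row per stratum
#'   with `site_id`, `year`, `slope` (cm/day), `intercept` (cm at
#'   `center_day`), `center_day`, `n_obs`, `residual_sd`, `r_squared`.
#' @export
fit_phenology <- function(study, min_n = 3) {
  nests <- if (inherits(study, "nest_study")) study$nests else study
  req <- c("site_id", "year", "measurement_day", "grass_height_mean")
  if (!all(req %in% names(nests)))
    stop("input must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  nests <- nests[!is.na(nests$measurement_day) &
                 !is.na(nests$grass_height_mean), , drop = FALSE]
  key <- interaction(nests$site_id, nests$year, drop = TRUE)
  sizes <- table(key)
  small <- names(sizes)[sizes < min_n]
  if (length(small))
    stop("strata below the minimum of ", min_n, " nests: ",
         paste(small, collapse = ", "), call. = FALSE)

  fits <- lapply(split(nests, key), function(d) {
    ctr <- stats::median(d$measurement_day)
    day_c <- d$measurement_day - ctr
    fit <- stats::lm(grass_height_mean ~ day_c, data = cbind(d, day_c = day_c))
    res <- stats::residuals(fit)
    resid_sd <- sqrt(sum(res^2) / stats::df.residual(fit))
    sst <- sum((d$grass_height_mean - mean(d$grass_height_mean))^2)
    data.frame(
      site_id = d$site_id[1], year = d$year[1],
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      center_day = ctr,
      n_obs = nrow(d),
      residual_sd = resid_sd,
      r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("phenology_fits", "data.frame")
  out
}

#' True phenology slopes of a simulated study, as a fits table
#'
#' Repackages the simulator's latent per-stratum phenology lines in the
#' same form as [fit_phenology()] output, so corrections can be computed
#' with the true rather than estimated growth slopes (useful for
#' exactness checks).
#'
#' @param study a simulated `"nest_study"` (must carry `strata` truths).
#' @return A `"phenology_fits"` data frame with the true slopes.
#' @export
true_phenology_fits <- function(study) {
  stopifnot(inherits(study, "nest_study"))
  st <- study$strata
  if (is.null(st$phen_slope))
    stop("study does not carry simulator stratum truths", call. = FALSE)
  mid <- (study$config$season_start_day + study$config$season_end_day) / 2
  out <- data.frame(
    site_id = st$site_id, year = st$year,
    slope = st$phen_slope, intercept = st$phen_intercept,
    center_day = mid, n_obs = NA_integer_,
    residual_sd = NA_real_, r_squared = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("phenology_fits", "data.frame")
  out
}

#' Correct measured grass heights to predicted hatch date
#'
#' Applies the phenology correction
#' `corrected = measured - (measurement_day - hatch_day) * slope`,
#' where `slope` is the nest's stratum growth rate from `fits`. A nest
#' measured after its hatch date in a growing season therefore has its
#' height revised downward to what it would have been at hatch.
#'
#' @param study a `"nest_study"` (or data frame with `nest_id`, `site_id`,
#'   `year`, `measurement_day`, `hatch_day`, `grass_height_mean`, and
#'   optionally `fate` / `true_height_at_hatch`).
#' @param fits a `"phenology_fits"` table covering every stratum present,
#'   e.g. from [fit_phenology()].
#' @return A data frame of class `"corrected_heights"`: per nest, the
#'   measured height, `grass_height_corrected`, the signed `correction`
#'   (corrected minus measured), and the stratum slope used. Nests with a
#'   missing measurement day are excluded with a message.
#' @export
correct_heights <- function(study, fits) {
  nests <- if (inherits(study, "nest_study")) study$nests else study
  stopifnot(is.data.frame(fits))
  miss <- is.na(nests$measurement_day)
  if (any(miss)) {
    message("excluding ", sum(miss), " nest(s) with missing measurement day: ",
            paste(utils::head(nests$nest_id[miss], 5), collapse = ", "))
    nests <- nests[!miss, , drop = FALSE]
  }
  key_n <- paste(nests$site_id, nests$year, sep = ":")
  key_f <- paste(fits$site_id, fits$year, sep = ":")
  idx <- match(key_n, key_f)
  if (anyNA(idx))
    stop("no phenology fit for strata: ",
         paste(unique(key_n[is.na(idx)]), collapse = ", "), call. = FALSE)
  slope <- fits$slope[idx]
  lag <- nests$measurement_day - nests$hatch_day
  out <- data.frame(
    nest_id = nests$nest_id,
    site_id = nests$site_id,
    year = nests$year,
    measurement_day = nests$measurement_day,
    hatch_day = nests$hatch_day,
    grass_height_mean = nests$grass_height_mean,
    grass_height_corrected = nests$grass_height_mean - lag * slope,
    correction = -lag * slope,
    slope_used = slope,
    stringsAsFactors = FALSE
  )
  if (!is.null(nests$fate)) out$fate <- nests$fate
  if (!is.null(nests$true_height_at_hatch))
    out$true_height_at_hatch <- nests$true_height_at_hatch
  class(out) <- c("corrected_heights", "data.frame")
  out
}

#' Summarize phenology corrections
#'
#' @param cd a `"corrected_heights"` data frame from [correct_heights()].
#' @return A list with `mean_correction` (signed, cm), `mean_abs_correction`
#'   and `sd_abs_correction` (cm). With a fate-date protocol in a growing
#'   season the signed mean is typically negative: most nests are measured
#'   after hatch date, so heights are revised downward.
#' @export
summarize_corrections <- function(cd) {
  stopifnot(is.data.frame(cd), nrow(cd) > 0)
  corr <- cd$correction
  list(
    mean_correction = mean(corr),
    mean_abs_correction = mean(abs(corr)),
    sd_abs_correction = stats::sd(abs(corr))
  )
}
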