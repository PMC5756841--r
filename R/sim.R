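#' Configuration for a synthetic multi-site nest study
#'
#' Collects the generative parameters of a simulated ground-nest study:
#' stratum structure (study site x year), season window, within-season
#' linear grass growth, daily nest survival on the logit scale, the
#' nest-visit schedule, and the vegetation-measurement protocol.
#'
#' The defaults describe a range-wide sage-grouse-like study: 24 study
#' site-years of ~50 nests each, a 27-day incubation period, grass around
#' 15 cm at the season midpoint growing 0.3 cm/day, daily nest survival
#' near 0.967 (so roughly 40% of nests hatch), and the biased fate-date
#' measurement protocol with no true effect of grass height on survival —
#' the regime in which measurement timing alone manufactures an apparent
#' concealment effect.
#'
#' @param n_sites number of study sites.
#' @param n_years number of years; strata are all site x year combinations.
#' @param nests_per_stratum nests simulated in each stratum.
#' @param season_start_day,season_end_day season window as ordinal
#'   day-of-year (days since January 1). Nest initiation is uniform on
#'   `season_start_day : (season_end_day - incubation_days)`.
#' @param incubation_days length of incubation; hatch day is initiation
#'   day plus `incubation_days`.
#' @param beta0_logit intercept of daily survival on the logit scale.
#' @param beta_grass_surv true effect (per cm) of grass height at hatch
#'   date on logit daily survival. Grass height is centered at
#'   `grass_intercept_mean` inside the survival simulation so that
#'   `beta0_logit` is the logit daily survival of an average nest.
#' @param grass_intercept_mean,grass_intercept_sd mean and between-stratum
#'   SD of grass height (cm) at the season midpoint.
#' @param grass_slope_mean,grass_slope_sd mean and between-stratum SD of
#'   the within-season growth rate (cm/day).
#' @param nest_height_sd SD (cm) of a nest's persistent deviation from its
#'   stratum phenology line.
#' @param replicate_sd SD (cm) of a single height measurement around the
#'   nest's phenology line at the measurement date.
#' @param n_replicates height measurements taken per nest (field studies
#'   use 8-20 samples along transects crossing at the nest shrub).
#' @param visit_interval_days days between successive nest checks.
#' @param protocol when vegetation is measured: `"FATE_DATE"` (the day the
#'   nest's fate is discovered — biased), `"HATCH_DATE"` (the predicted
#'   hatch day regardless of fate — unbiased), or `"SCHEDULED"`
#'   (hatch day plus Gaussian jitter with SD `scheduled_lag_sd`).
#' @param scheduled_lag_sd SD in days of the `"SCHEDULED"` timing jitter.
#' @param discovery_delay days after initiation at which nests are found;
#'   nests failing before discovery are never observed and are dropped.
#' @param seed integer RNG seed; mandatory for [simulate_study()].
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_study()]
#' @export
sim_config <- function(n_sites = 4,
                       n_years = 6,
                       nests_per_stratum = 50,
                       season_start_day = 105,
                       season_end_day = 170,
                       incubation_days = 27,
                       beta0_logit = stats::qlogis(0.967),
                       beta_grass_surv = 0,
                       grass_intercept_mean = 15,
                       grass_intercept_sd = 3,
                       grass_slope_mean = 0.3,
                       grass_slope_sd = 0.1,
                       nest_height_sd = 4,
                       replicate_sd = 3,
                       n_replicates = 20,
                       visit_interval_days = 4,
                       protocol = c("FATE_DATE", "HATCH_DATE", "SCHEDULED"),
                       scheduled_lag_sd = 2,
                       discovery_delay = 0,
                       seed = NULL) {
  protocol <- match.arg(protocol)
  cfg <- list(
    n_sites = n_sites, n_years = n_years,
    nests_per_stratum = nests_per_stratum,
    season_start_day = season_start_day, season_end_day = season_end_day,
    incubation_days = incubation_days,
    beta0_logit = beta0_logit, beta_grass_surv = beta_grass_surv,
    grass_intercept_mean = grass_intercept_mean,
    grass_intercept_sd = grass_intercept_sd,
    grass_slope_mean = grass_slope_mean, grass_slope_sd = grass_slope_sd,
    nest_height_sd = nest_height_sd, replicate_sd = replicate_sd,
    n_replicates = n_replicates,
    visit_interval_days = visit_interval_days,
    protocol = protocol, scheduled_lag_sd = scheduled_lag_sd,
    discovery_delay = discovery_delay, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_sites", "n_years", "nests_per_stratum", "incubation_days",
              "n_replicates", "visit_interval_days")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a single integer >= 1", nm), call. = FALSE)
  }
  sds <- c("grass_intercept_sd", "grass_slope_sd", "nest_height_sd",
           "replicate_sd", "scheduled_lag_sd")
  for (nm in sds) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop(sprintf("`%s` must be a single number >= 0", nm), call. = FALSE)
  }
  if (cfg$season_end_day <= cfg$season_start_day + cfg$incubation_days)
    stop("infeasible season window: `season_end_day` must exceed ",
         "`season_start_day` + `incubation_days` so at least one full ",
         "incubation period fits in the season", call. = FALSE)
  if (cfg$discovery_delay < 0)
    stop("`discovery_delay` must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  strata: %d sites x %d years, %d nests each (%d nests)\n",
              x$n_sites, x$n_years, x$nests_per_stratum,
              x$n_sites * x$n_years * x$nests_per_stratum))
  cat(sprintf("  season days %d-%d, incubation %d days, visits every %d days\n",
              x$season_start_day, x$season_end_day, x$incubation_days,
              x$visit_interval_days))
  cat(sprintf("  daily survival: logit = %.3f %+.3f x (grass height - %.1f cm)\n",
              x$beta0_logit, x$beta_grass_surv, x$grass_intercept_mean))
  cat(sprintf("  grass: %.1f cm (SD %.1f) at midseason, %.2f cm/day (SD %.2f)\n",
              x$grass_intercept_mean, x$grass_intercept_sd,
              x$grass_slope_mean, x$grass_slope_sd))
  cat(sprintf("  measurement protocol: %s, %d replicates (SD %.1f cm)\n",
              x$protocol, x$n_replicates, x$replicate_sd))
  invisible(x)
}

#' Simulate a multi-site nest study
#'
#' Draws a complete synthetic nest dataset under `config`: per-stratum
#' grass phenology lines (linear in day), nest initiation days, daily
#' Bernoulli survival through incubation with logit-linear dependence on
#' the nest's true grass height at hatch date, periodic nest visits until
#' fate resolution, and replicated grass-height measurements taken at a
#' date set by the measurement protocol. Failure is absorbing: a failed
#' nest is discovered at the first visit on or after its (latent) failure
#' day and is not visited afterwards.
#'
#' @param config a [sim_config()]; `config$seed` must be set.
#' @return An object of class `"nest_study"`: a list with components
#'   * `nests`: data frame with one row per nest (`nest_id`, `site_id`,
#'     `year`, `initiation_day`, `hatch_day`, `fate`, `end_day`,
#'     `measurement_day`, `grass_heights` list column of replicate
#'     measurements, `grass_height_mean`, and the simulator-only latent
#'     `true_height_at_hatch`);
#'   * `visits`: data frame (`nest_id`, `day`, `state`) of the encounter
#'     histories, states `"ALIVE"`/`"FAILED"`;
#'   * `strata`: data frame of per-stratum true phenology intercepts (cm at
#'     season midpoint) and slopes (cm/day), simulator-only;
#'   * `config`: the generating configuration.
#' @examples
#' study <- simulate_study(sim_config(n_sites = 2, n_years = 1,
#'                                    nests_per_stratum = 20, seed = 1))
#' table(study$nests$fate)
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("`config` must be a sim_config object", call. = FALSE)
  validate_sim_config(config)
  if (is.null(config$seed))
    stop("`config$seed` must be set for reproducible simulation",
         call. = FALSE)
  withr::with_seed(as.integer(config$seed), simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  midseason <- (cfg$season_start_day + cfg$season_end_day) / 2
  strata <- expand.grid(
    site_id = sprintf("S%02d", seq_len(cfg$n_sites)),
    year = 2000L + seq_len(cfg$n_years),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  strata$phen_intercept <- stats::rnorm(nrow(strata),
                                        cfg$grass_intercept_mean,
                                        cfg$grass_intercept_sd)
  strata$phen_slope <- stats::rnorm(nrow(strata),
                                    cfg$grass_slope_mean,
                                    cfg$grass_slope_sd)

  init_window <- cfg$season_start_day:(cfg$season_end_day - cfg$incubation_days)
  nest_rows <- vector("list", nrow(strata))
  visit_rows <- vector("list", nrow(strata))
  nest_counter <- 0L

  for (s in seq_len(nrow(strata))) {
    n <- cfg$nests_per_stratum
    a <- strata$phen_intercept[s]
    b <- strata$phen_slope[s]

    initiation <- sample(init_window, n, replace = TRUE)
    hatch <- initiation + cfg$incubation_days
    nest_dev <- stats::rnorm(n, 0, cfg$nest_height_sd)
    true_h_hatch <- a + b * (hatch - midseason) + nest_dev

    s_daily <- stats::plogis(cfg$beta0_logit +
      cfg$beta_grass_surv * (true_h_hatch - cfg$grass_intercept_mean))
    # first failure day offset ~ Geometric(1 - S); beyond incubation = hatched
    p_fail <- pmax(1 - s_daily, 1e-300)
    t_fail <- stats::rgeom(n, p_fail) + 1
    fate <- ifelse(t_fail > cfg$incubation_days, "HATCHED", "FAILED")
    fail_day <- ifelse(fate == "FAILED", initiation + t_fail, NA_integer_)
    end_day <- ifelse(fate == "FAILED", fail_day, hatch)

    found_day <- initiation + cfg$discovery_delay
    observed <- fate == "HATCHED" | is.na(fail_day) | fail_day > found_day

    meas_jitter <- if (cfg$protocol == "SCHEDULED")
      round(stats::rnorm(n, 0, cfg$scheduled_lag_sd)) else rep(0L, n)

    vis_s <- vector("list", n)
    discovery <- integer(n)
    for (i in seq_len(n)) {
      if (!observed[i]) next
      vdays <- seq(found_day[i], hatch[i], by = cfg$visit_interval_days)
      if (vdays[length(vdays)] < hatch[i]) vdays <- c(vdays, hatch[i])
      if (fate[i] == "FAILED") {
        fd_obs <- min(vdays[vdays >= fail_day[i]])
        vdays <- c(vdays[vdays < fail_day[i]], fd_obs)
        states <- c(rep("ALIVE", length(vdays) - 1L), "FAILED")
      } else {
        fd_obs <- hatch[i]
        states <- rep("ALIVE", length(vdays))
      }
      discovery[i] <- fd_obs
      vis_s[[i]] <- data.frame(day = as.integer(vdays), state = states,
                               stringsAsFactors = FALSE)
    }

    measurement_day <- switch(cfg$protocol,
      FATE_DATE = discovery,
      HATCH_DATE = hatch,
      SCHEDULED = pmax(found_day, hatch + meas_jitter)
    )

    height_line <- a + b * (measurement_day - midseason) + nest_dev
    reps <- matrix(stats::rnorm(n * cfg$n_replicates, 0, cfg$replicate_sd),
                   nrow = n) + height_line

    keep <- which(observed)
    ids <- sprintf("N%05d", nest_counter + seq_along(keep))
    nest_counter <- nest_counter + length(keep)

    nest_rows[[s]] <- data.frame(
      nest_id = ids,
      site_id = strata$site_id[s],
      year = strata$year[s],
      initiation_day = as.integer(initiation[keep]),
      hatch_day = as.integer(hatch[keep]),
      fate = fate[keep],
      end_day = as.integer(end_day[keep]),
      measurement_day = as.integer(measurement_day[keep]),
      grass_height_mean = rowMeans(reps)[keep],
      true_height_at_hatch = true_h_hatch[keep],
      stringsAsFactors = FALSE
    )
    nest_rows[[s]]$grass_heights <- lapply(keep, function(i) unname(reps[i, ]))
    visit_rows[[s]] <- do.call(rbind, lapply(seq_along(keep), function(j) {
      v <- vis_s[[keep[j]]]
      data.frame(nest_id = ids[j], day = v$day, state = v$state,
                 stringsAsFactors = FALSE)
    }))
  }

  nests <- do.call(rbind, nest_rows)
  rownames(nests) <- NULL
  visits <- do.call(rbind, visit_rows)
  rownames(visits) <- NULL

  structure(list(nests = nests, visits = visits, strata = strata,
                 config = cfg),
            class = "nest_study")
}

#' @export
print.nest_study <- function(x, ...) {
  cat("<nest_study>\n")
  cat(sprintf("  %d nests in %d strata (%d hatched, %d failed)\n",
              nrow(x$nests), nrow(x$strata),
              sum(x$nests$fate == "HATCHED"), sum(x$nests$fate == "FAILED")))
  cat(sprintf("  %d visits; measurement protocol: %s\n", nrow(x$visits),
              if (is.null(x$config)) "(unknown: read from file)"
              else x$config$protocol))
  invisible(x)
}

#' Write / read a nest study as CSV
#'
#' `write_study()` writes `nests.csv` (replicate heights semicolon-joined
#' in a single column) and `visits.csv` to `dir`; `read_study()` rebuilds
#' a `"nest_study"` from those files. A round trip preserves the analysis
#' columns; the simulator-only stratum truths and the generating
#' configuration are not stored in the CSVs.
#'
#' @param study a `"nest_study"` object.
#' @param dir output directory, created if needed.
#' @return `write_study()`: invisibly, the two file paths.
#'   `read_study()`: a `"nest_study"` with `config = NULL` and `strata`
#'   inferred from the data.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "nest_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nests <- study$nests
  # 17 significant digits so doubles round-trip exactly through the CSV
  nests$grass_heights <- vapply(
    nests$grass_heights,
    function(h) paste(sprintf("%.17g", h), collapse = ";"),
    character(1)
  )
  for (col in intersect(c("grass_height_mean", "true_height_at_hatch"),
                        names(nests))) {
    nests[[col]] <- sprintf("%.17g", nests[[col]])
  }
  nests_path <- file.path(dir, "nests.csv")
  visits_path <- file.path(dir, "visits.csv")
  utils::write.csv(nests, nests_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(study$visits, visits_path, row.names = FALSE, quote = TRUE)
  invisible(c(nests = nests_path, visits = visits_path))
}

#' @param nests_path,visits_path paths to the two CSV files.
#' @rdname write_study
#' @export
read_study <- function(nests_path, visits_path) {
  nests <- utils::read.csv(nests_path, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  if ("grass_heights" %in% names(nests)) {
    nests$grass_heights <- lapply(strsplit(nests$grass_heights, ";"),
                                  as.numeric)
  }
  strata <- unique(nests[, c("site_id", "year")])
  rownames(strata) <- NULL
  structure(list(nests = nests, visits = visits, strata = strata,
                 config = NULL),
            class = "nest_study")
}
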