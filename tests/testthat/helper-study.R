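# shared fixtures: all built in code at test time

# small default-mechanism study (fate-date protocol, no true grass effect)
small_config <- function(seed = 1, n_sites = 2, n_years = 2,
                         nests_per_stratum = 30, ...) {
  sim_config(n_sites = n_sites, n_years = n_years,
             nests_per_stratum = nests_per_stratum, seed = seed, ...)
}

# hand-built minimal study object for interval-construction tests
make_study <- function(nests, visits, config = NULL, strata = NULL) {
  if (is.null(strata)) {
    strata <- unique(nests[, c("site_id", "year")])
    rownames(strata) <- NULL
  }
  structure(list(nests = nests, visits = visits, strata = strata,
                 config = config),
            class = "nest_study")
}

make_nest <- function(nest_id = "N1", site_id = "S01", year = 2001L,
                      initiation_day = 100L, incubation = 27L,
                      fate = "HATCHED", grass = 15) {
  data.frame(nest_id = nest_id, site_id = site_id, year = year,
             initiation_day = initiation_day,
             hatch_day = initiation_day + incubation,
             fate = fate, end_day = initiation_day + incubation,
             measurement_day = initiation_day + incubation,
             grass_height_mean = grass,
             stringsAsFactors = FALSE)
}

# join corrected heights onto the nests table for survival fits
with_corrected <- function(study, cd) {
  nests <- study$nests
  nests$grass_height_corrected <-
    cd$grass_height_corrected[match(nests$nest_id, cd$nest_id)]
  nests
}

# brute-force interval likelihood: explicit sum over failure-day placements
enumerate_interval_lik <- function(X, beta, outcome) {
  s <- plogis(as.vector(X %*% beta))
  if (outcome == "SURVIVED") return(prod(s))
  k <- length(s)
  tot <- 0
  for (fail_at in seq_len(k)) {
    tot <- tot + prod(s[seq_len(fail_at - 1)]) * (1 - s[fail_at])
  }
  tot
}

# independent D+ and exact permutation p, written against stats::ecdf
oracle_ks <- function(hatched, failed) {
  dplus <- function(f, h) {
    pts <- sort(unique(c(f, h)))
    max(ecdf(f)(pts) - ecdf(h)(pts))
  }
  d <- dplus(failed, hatched)
  pool <- c(failed, hatched)
  m <- length(failed)
  combos <- utils::combn(length(pool), m)
  perm <- apply(combos, 2, function(ii) dplus(pool[ii], pool[-ii]))
  list(statistic = d, p_value = mean(perm >= d - 1e-12))
}

# scaled-down MCMC used throughout the simulation experiments
test_mcmc <- function(seed, iter = 2000, warmup = 1000) {
  mcmc_control(chains = 3, iter = iter, warmup = warmup, seed = seed)
}

grass_summary <- function(post, covariate) {
  post$summary[post$summary$parameter == covariate, ]
}
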