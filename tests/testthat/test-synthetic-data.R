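test_that("config validation catches infeasible and degenerate settings", {
  expect_error(sim_config(season_start_day = 100, season_end_day = 120),
               "season window")
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(nests_per_stratum = 2.5), "nests_per_stratum")
  expect_error(sim_config(replicate_sd = -1), "replicate_sd")
  expect_error(simulate_study(sim_config()), "seed")
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_study(small_config(seed = 7))
  b <- simulate_study(small_config(seed = 7))
  expect_identical(a, b)
  c <- simulate_study(small_config(seed = 8))
  expect_false(identical(a$nests$grass_height_mean,
                         c$nests$grass_height_mean))
})

test_that("every simulated nest satisfies the structural invariants", {
  st <- simulate_study(small_config(seed = 11))
  n <- st$nests
  expect_equal(n$hatch_day, n$initiation_day + st$config$incubation_days)
  expect_true(all(n$end_day <= n$hatch_day))
  expect_true(all(n$end_day[n$fate == "HATCHED"] ==
                    n$hatch_day[n$fate == "HATCHED"]))
  expect_equal(n$grass_height_mean,
               vapply(n$grass_heights, mean, numeric(1)))
  expect_true(all(lengths(n$grass_heights) == st$config$n_replicates))
  # nest count equals the sum over strata and all strata are represented
  expect_equal(nrow(n),
               st$config$n_sites * st$config$n_years *
                 st$config$nests_per_stratum)
  expect_setequal(paste(n$site_id, n$year),
                  paste(st$strata$site_id, st$strata$year))
  # visits: strictly increasing days, failure absorbing and final
  for (v in split(st$visits, st$visits$nest_id)) {
    expect_false(is.unsorted(v$day, strictly = TRUE))
    fails <- which(v$state == "FAILED")
    expect_lte(length(fails), 1)
    if (length(fails)) expect_equal(fails, nrow(v))
  }
  # measurement day never precedes the first visit
  first_visit <- vapply(split(st$visits$day, st$visits$nest_id), min,
                        numeric(1))
  expect_true(all(n$measurement_day >= first_visit[n$nest_id]))
})

test_that("measurement protocols set the measurement day as defined", {
  st_h <- simulate_study(small_config(seed = 3, protocol = "HATCH_DATE"))
  expect_equal(st_h$nests$measurement_day, st_h$nests$hatch_day)

  st_f <- simulate_study(small_config(seed = 3, protocol = "FATE_DATE"))
  last_visit <- vapply(split(st_f$visits$day, st_f$visits$nest_id), max,
                       numeric(1))
  expect_equal(st_f$nests$measurement_day,
               unname(last_visit[st_f$nests$nest_id]))

  st_s <- simulate_study(small_config(seed = 3, protocol = "SCHEDULED",
                                      scheduled_lag_sd = 2))
  expect_true(all(abs(st_s$nests$measurement_day - st_s$nests$hatch_day)
                  <= 10))
})

test_that("fate-date protocol delays measurement at successful nests by the predicted amount", {
  cfg <- sim_config(n_sites = 5, n_years = 4, nests_per_stratum = 100,
                    grass_slope_mean = 0.3, seed = 21)
  st <- simulate_study(cfg)
  n <- st$nests
  gap <- mean(n$measurement_day[n$fate == "HATCHED"] -
                n$initiation_day[n$fate == "HATCHED"]) -
         mean(n$measurement_day[n$fate == "FAILED"] -
                n$initiation_day[n$fate == "FAILED"])
  expect_gt(gap, 0)

  # analytic oracle: with no grass effect, daily survival is approximately
  # constant; failure offset t has truncated-geometric weight S^(t-1)(1-S),
  # discovery is the first visit at/after t under the 4-day schedule with a
  # forced hatch-day visit, and hatched nests are measured at hatch (offset
  # = incubation). The expected gap follows by enumeration over t.
  inc <- cfg$incubation_days
  iv <- cfg$visit_interval_days
  s_bar <- plogis(cfg$beta0_logit)
  t_seq <- seq_len(inc)
  w <- s_bar^(t_seq - 1) * (1 - s_bar)
  w <- w / sum(w)
  discover <- pmin(ceiling(t_seq / iv) * iv, inc)
  expected_gap <- inc - sum(w * discover)
  expect_lt(abs(gap - expected_gap), 1.0)
})

test_that("realized hatch proportion matches the closed-form survival product", {
  cfg <- sim_config(n_sites = 2, n_years = 1, nests_per_stratum = 2500,
                    beta0_logit = qlogis(0.96), beta_grass_surv = 0,
                    seed = 5)
  st <- simulate_study(cfg)
  prop <- mean(st$nests$fate == "HATCHED")
  expected <- 0.96^27
  mc_se <- sqrt(expected * (1 - expected) / nrow(st$nests))
  expect_lt(abs(prop - expected), 3 * mc_se)
})

test_that("hatch proportion increases monotonically in the survival intercept", {
  props <- vapply(c(0.90, 0.95, 0.99), function(s) {
    st <- simulate_study(small_config(seed = 9, beta0_logit = qlogis(s),
                                      nests_per_stratum = 500))
    mean(st$nests$fate == "HATCHED")
  }, numeric(1))
  expect_true(all(diff(props) > 0))
})

test_that("hatched and failed heights are exchangeable under the unbiased protocol", {
  # with no true grass effect and hatch-date measurement, the two-sample
  # KS p-values should look uniform across replicate simulations
  pvals <- vapply(1:30, function(r) {
    st <- simulate_study(sim_config(n_sites = 2, n_years = 1,
                                    nests_per_stratum = 100,
                                    protocol = "HATCH_DATE",
                                    seed = 600 + r))
    n <- st$nests
    suppressWarnings(stats::ks.test(
      n$grass_height_mean[n$fate == "HATCHED"],
      n$grass_height_mean[n$fate == "FAILED"]))$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # ... while the biased protocol separates them
  st <- simulate_study(sim_config(n_sites = 3, n_years = 2,
                                  nests_per_stratum = 100, seed = 77))
  n <- st$nests
  expect_gt(mean(n$grass_height_mean[n$fate == "HATCHED"]),
            mean(n$grass_height_mean[n$fate == "FAILED"]))
})

test_that("discovery delay drops nests that fail before they are found", {
  st0 <- simulate_study(small_config(seed = 13))
  st5 <- simulate_study(small_config(seed = 13, discovery_delay = 5))
  expect_lt(nrow(st5$nests), nrow(st0$nests))
  first_visit <- vapply(split(st5$visits$day, st5$visits$nest_id), min,
                        numeric(1))
  expect_equal(unname(first_visit[st5$nests$nest_id]),
               st5$nests$initiation_day + 5)
})

test_that("CSV writer and reader round-trip the analysis columns", {
  st <- simulate_study(small_config(seed = 19))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  rt <- read_study(paths["nests"], paths["visits"])
  for (col in c("nest_id", "site_id", "year", "initiation_day",
                "hatch_day", "fate", "end_day", "measurement_day")) {
    expect_identical(rt$nests[[col]], st$nests[[col]])
  }
  expect_equal(rt$nests$grass_height_mean, st$nests$grass_height_mean)
  expect_equal(rt$nests$grass_heights, st$nests$grass_heights)
  expect_identical(rt$visits, st$visits)
  # downstream phenology results identical on the round-tripped data
  expect_equal(as.data.frame(fit_phenology(rt)),
               as.data.frame(fit_phenology(st)))
})
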