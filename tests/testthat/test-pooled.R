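fake_lmm <- function(logLik, fate_effect, method = "ML", k = 5,
                     n = 800, random = "slope") {
  structure(list(logLik = logLik, fate_effect = fate_effect,
                 method = method, k = k, n_obs = n, random = random),
            class = "lmm_fit")
}

sim_lmm_data <- function(n_strata, n_per, int_sd, slope_sd, resid_sd,
                         fate_shift = 0, seed = 1) {
  withr::with_seed(seed, {
    stratum <- rep(sprintf("st%02d", seq_len(n_strata)), each = n_per)
    a <- rep(rnorm(n_strata, 15, int_sd), each = n_per)
    b <- rep(rnorm(n_strata, 0.3, slope_sd), each = n_per)
    day <- sample(120:170, n_strata * n_per, replace = TRUE)
    fate <- rep(c("HATCHED", "FAILED"), length.out = n_strata * n_per)
    gh <- a + b * (day - 145) + fate_shift * (fate == "HATCHED") +
      rnorm(n_strata * n_per, 0, resid_sd)
    data.frame(gh = gh, day = day, fate = fate, stratum = stratum,
               stringsAsFactors = FALSE)
  })
}

test_that("zero between-stratum variance reduces the mixed model to OLS", {
  d <- sim_lmm_data(2, 60, int_sd = 0, slope_sd = 0, resid_sd = 2,
                    seed = 5)
  fit <- fit_lmm(d, random = "intercept", method = "ML")
  ols <- lm(gh ~ I(day - median(day)), data = d)
  expect_equal(unname(fit$fixed), unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$singular)
  # stratum sd estimated at/near the boundary
  expect_lt(fit$varcorr$sdcor[fit$varcorr$grp == "stratum"][1], 0.1)
})

test_that("variance components are recovered from simulated strata", {
  d <- sim_lmm_data(60, 40, int_sd = 3, slope_sd = 0.1, resid_sd = 2,
                    seed = 11)
  fit <- fit_lmm(d, random = "slope", method = "REML")
  vc <- fit$varcorr
  sd_int <- vc$sdcor[vc$grp == "stratum" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  sd_slp <- vc$sdcor[vc$grp == "stratum" & vc$var1 == "day_c" &
                       is.na(vc$var2)]
  sd_res <- vc$sdcor[vc$grp == "Residual"]
  expect_lt(abs(sd_int - 3) / 3, 0.25)
  expect_lt(abs(sd_slp - 0.1) / 0.1, 0.25)
  expect_lt(abs(sd_res - 2) / 2, 0.25)
})

test_that("mixed-model likelihood matches an independent implementation", {
  skip_if_not_installed("nlme")
  d <- sim_lmm_data(10, 30, int_sd = 3, slope_sd = 0.1, resid_sd = 2,
                    seed = 13)
  fit <- fit_lmm(d, random = "slope", method = "ML")
  d$day_c <- d$day - median(d$day)
  ref <- nlme::lme(gh ~ day_c, random = ~ day_c | stratum, data = d,
                   method = "ML")
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$fixed), unname(nlme::fixef(ref)),
               tolerance = 1e-4)
})

test_that("log-likelihood and slope are invariant to re-centering day", {
  d <- sim_lmm_data(8, 30, int_sd = 2, slope_sd = 0.05, resid_sd = 2,
                    seed = 17)
  f1 <- fit_lmm(d, random = "slope", method = "ML")
  d2 <- d
  d2$day <- d$day + 31
  f2 <- fit_lmm(d2, random = "slope", method = "ML")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  expect_equal(f1$fixed[["day_c"]], f2$fixed[["day_c"]],
               tolerance = 1e-6)
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, k = 3, n = 1000),
               200 + 6 + 2 * 3 * 4 / (1000 - 3 - 1), tolerance = 1e-12)
  # large-n limit: correction term vanishes
  expect_equal(aicc(-100, k = 3, n = 1e8), 206, tolerance = 1e-5)
  expect_error(aicc(-100, k = 10, n = 11), "positive")
})

test_that("AICc ordering of random structures is invariant to height units", {
  d <- sim_lmm_data(12, 30, int_sd = 3, slope_sd = 0.1, resid_sd = 2,
                    seed = 19)
  gap_cm <- aicc(fit_lmm(d, "intercept", method = "REML")) -
    aicc(fit_lmm(d, "slope", method = "REML"))
  d_mm <- d
  d_mm$gh <- d$gh * 10
  gap_mm <- aicc(fit_lmm(d_mm, "intercept", method = "REML")) -
    aicc(fit_lmm(d_mm, "slope", method = "REML"))
  expect_equal(gap_cm, gap_mm, tolerance = 1e-4)
  expect_gt(gap_cm, 0)  # heterogeneous slopes favour the slope structure
})

test_that("likelihood-ratio test maps statistics to chi-squared tails", {
  # equal likelihoods -> statistic 0, p = 1
  t0 <- lrt_fate(fake_lmm(-100, FALSE), fake_lmm(-100, TRUE, k = 6))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # a 1-df chi-squared of 2.74 sits at p = 0.098
  t1 <- lrt_fate(fake_lmm(-100, FALSE), fake_lmm(-100 + 2.74 / 2, TRUE,
                                                 k = 6))
  expect_equal(t1$statistic, 2.74, tolerance = 1e-12)
  expect_equal(round(t1$p_value, 3), 0.098)
  # guard rails
  expect_error(lrt_fate(fake_lmm(-100, FALSE), fake_lmm(-100.1, TRUE)),
               "below null")
  expect_error(lrt_fate(fake_lmm(-100, FALSE, method = "REML"),
                        fake_lmm(-99, TRUE, method = "REML")), "ML")
  expect_error(lrt_fate(fake_lmm(-100, TRUE), fake_lmm(-99, TRUE)),
               "fate")
})

test_that("fate LRT detects a true difference and respects nesting", {
  d <- sim_lmm_data(8, 40, int_sd = 2, slope_sd = 0.05, resid_sd = 2,
                    fate_shift = 1.5, seed = 23)
  lrt <- lrt_fate(fit_lmm(d, "slope", FALSE, "ML"),
                  fit_lmm(d, "slope", TRUE, "ML"))
  expect_gt(lrt$statistic, 0)
  expect_lt(lrt$p_value, 0.01)
})

test_that("one-sided KS statistic and p behave on canonical cases", {
  x <- c(10, 12, 14, 16, 18)
  same <- ks_one_sided(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # a large upward shift of hatched heights is overwhelming evidence
  withr::with_seed(31, {
    f <- rnorm(100, 15, 3)
    h <- f + 10
  })
  shift <- ks_one_sided(h, f)
  expect_lt(shift$p_value, 0.001)
  expect_false(shift$exact)

  # direction: the test looks for hatched stochastically larger, so a
  # *downward* shift should give no evidence at all
  expect_gt(ks_one_sided(f - 10, f)$p_value, 0.9)

  # ties are handled deterministically at pooled jump points
  tied <- ks_one_sided(c(1, 1, 2, 2), c(1, 2, 2, 3))
  expect_true(tied$statistic >= 0 && tied$p_value <= 1)
})

test_that("exact permutation p matches an independent enumeration", {
  withr::with_seed(37, {
    cases <- list(c(3, 4), c(5, 5), c(6, 4), c(2, 7))
    for (mn in cases) {
      h <- rnorm(mn[1], 16, 3)
      f <- rnorm(mn[2], 15, 3)
      ours <- ks_one_sided(h, f)
      oracle <- oracle_ks(h, f)
      expect_true(ours$exact)
      expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-12)
      expect_equal(ours$p_value, oracle$p_value, tolerance = 1e-12)
    }
  })
})

test_that("asymptotic branch agrees with the reference implementation and the exact tail", {
  withr::with_seed(41, {
    h <- rnorm(40, 16, 3)
    f <- rnorm(45, 15, 3)
  })
  ours <- ks_one_sided(h, f)
  ref <- suppressWarnings(stats::ks.test(f, h, alternative = "greater",
                                         exact = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

  # at moderate small samples the asymptotic tail tracks the exact one
  withr::with_seed(43, {
    h7 <- rnorm(7, 16, 3)
    f7 <- rnorm(7, 15, 3)
  })
  exact_p <- ks_one_sided(h7, f7)$p_value
  asym_p <- ks_one_sided(h7, f7, exact_limit = 0)$p_value
  expect_lt(abs(exact_p - asym_p), 0.05)
})

test_that("pooled data layouts pair heights with their reference dates", {
  st <- simulate_study(small_config(seed = 47))
  cd <- correct_heights(st, fit_phenology(st))
  pm <- pooled_data(cd, "measured")
  pc <- pooled_data(cd, "corrected")
  expect_equal(pm$gh, cd$grass_height_mean)
  expect_equal(pm$day, cd$measurement_day)
  expect_equal(pc$gh, cd$grass_height_corrected)
  expect_equal(pc$day, cd$hatch_day)
  expect_equal(nlevels(factor(pm$stratum)), nrow(st$strata))
})
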