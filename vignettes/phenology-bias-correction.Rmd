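---
title: "Phenology bias in nest-vegetation covariates: model, correction, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology bias in nest-vegetation covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nestpheno)
```

## The mechanism this package is about

Vegetation around ground nests is usually summarized as the mean of
replicated grass-height samples taken on a single visit. When that visit
happens on the day a nest's fate is resolved ("fate-date" sampling),
measurement timing becomes entangled with fate: a nest that hatches is
measured at the end of its ~27-day incubation, while a depredated nest
is measured at the visit where the failure was discovered, typically
one to three weeks earlier. If grass grows within the season at
β~grass~ cm/day, successful nests accrue roughly
β~grass~ × (incubation − mean failure time) extra centimetres that have
nothing to do with concealment. Regressing survival on such a covariate
manufactures a positive "grass effect" out of plant phenology.

`nestpheno` provides the full chain needed to study and undo this:
a generative simulator with the mechanism built in, the hatch-date
correction, a Bayesian daily nest-survival model, and pooled
mixed-model/likelihood-ratio/Kolmogorov–Smirnov comparisons.

## The simulator and what it emulates

`simulate_study()` draws, for each study-site × year stratum, a linear
phenology line: intercept (height at the season midpoint) ~
Normal(`grass_intercept_mean`, `grass_intercept_sd`) and growth slope ~
Normal(`grass_slope_mean`, `grass_slope_sd`). Each nest gets a uniform
initiation day (so that a full incubation fits in the season), a
persistent deviation from its stratum line (`nest_height_sd`), daily
Bernoulli survival with

logit(S) = `beta0_logit` + `beta_grass_surv` × (height at hatch − `grass_intercept_mean`),

visits every `visit_interval_days` from initiation with a confirmatory
visit at hatch, fate discovery at the first visit at/after the (latent)
failure day, and `n_replicates` height measurements drawn around the
nest's phenology line evaluated at the measurement date
(`replicate_sd` per sample). Protocols: `FATE_DATE` measures at fate
discovery, `HATCH_DATE` at the predicted hatch day regardless of fate,
`SCHEDULED` at hatch day plus Gaussian jitter.

Default parameter choices, with reasoning:

| parameter | default | why |
|---|---|---|
| `n_sites` × `n_years` | 4 × 6 = 24 strata | the scale of a pooled multi-study dataset (24 site-years) |
| `nests_per_stratum` | 50 | ~1200 nests total, a realistic pooled sample |
| `incubation_days` | 27 | sage-grouse incubation convention |
| `beta0_logit` | logit(0.967) | daily survival giving ~40% incubation success, matching pooled hatched fractions (~0.42) in range-wide data |
| `beta_grass_surv` | 0 | the null is the reference condition: any apparent effect is then attributable to protocol |
| `grass_intercept_mean` | 15 cm | typical live-grass height around nests |
| `grass_slope_mean` | 0.3 cm/day | a realistic spring growth rate; strong enough that fate-date timing matters |
| `nest_height_sd` / `replicate_sd` | 4 / 3 cm | within-stratum spatial variation vs. within-nest sampling noise |
| `n_replicates` | 20 | the common transect design (8–20 samples per nest in field studies) |
| `visit_interval_days` | 4 | field protocols rarely publish visit frequency; 4 days is a free parameter, not a claim |

What the simulator does **not** emulate: nonlinear growth or senescence,
spatial habitat structure, shrub cover, predator communities,
re-nesting, abandonment/censoring, and observer effects. Passing tests
therefore demonstrate that the *statistical machinery* behaves correctly
under the assumed structure — not that any particular field dataset
satisfies that structure.

Sign of corrections under `FATE_DATE`: hatched nests are measured at
hatch (zero lag), failed nests before hatch (negative lag), so
corrections are ≥ 0 and the mean correction is positive. Field datasets
in which most nests were measured *after* predicted hatch show negative
mean corrections instead; both are the same mechanism viewed from
different sides of the hatch date.

## The phenology correction

For each stratum, `fit_phenology()` regresses nest-mean measured height
on measurement day (OLS; the day covariate is centered at the stratum
median measurement day purely for conditioning — the slope is invariant).
`correct_heights()` then applies

corrected = measured − (measurement day − hatch day) × slope.

Design choices: the regression response is the nest *mean* (replicates
enter only through it); strata are site × year with independent
regressions (no pooling or shrinkage); strata with fewer than 3 nests
are an error, never silently pooled; slope uncertainty is *not*
propagated into downstream models (a deliberate two-stage plug-in,
matching standard practice — its main visible consequence is a small
extra stratum-level variance component in downstream analyses of
corrected heights).

## The daily nest-survival model

Encounter histories are reduced to inter-visit intervals. Over an
interval (a, b] the nest survives days a+1, …, b each with probability
S~t~, logit(S~t~) = β₀ + x′β. Because failure is absorbing, the interval
likelihood is exactly Π S~t~ for survival and 1 − Π S~t~ for failure
within the interval — the closed-form marginal over the unobserved
failure day. We marginalize rather than impute latent daily states (as
Gibbs-based implementations do); the two are equivalent for an absorbing
state, and marginalization removes latent-variable mixing concerns.
`test-survival-likelihood.R` pins this against brute-force enumeration
over all failure-day placements to 10⁻¹².

Covariates: numeric nest-level covariates are centered (not scaled), so
the grass coefficient stays per-cm and comparable across fits; nest age
(days since initiation) and its square may enter as day-varying terms,
centered at the mean exposure-day age; year can enter as a random
intercept with Normal(0, σ~year~) effects and a half-Normal(0, 5)
hyperprior on σ~year~ (the scale of plausible between-year logit shifts;
sampled as log σ with the Jacobian). All other coefficients get vague
Normal(0, 1000) priors.

Sampling is adaptive random-walk Metropolis: proposal covariance
refreshed from the second half of warmup, global scale tuned by
Robbins–Monro toward 0.3 acceptance (inside the 0.2–0.5 random-walk
band). The production path is compiled (`src/sampler.cpp`); an identical
R implementation (`run_mcmc()`) is exported and the test suite checks
the two agree on a common posterior and that the sampler reproduces a
known target (the prior, under a data-free likelihood). The default
configuration keeps 3 × 30,000 draws after 20,000 warmup per chain;
simulation experiments in the tests use 3 × 2,000 after 1,000, which is
sufficient for the 2–3 parameter models involved (R-hat ≤ 1.1, ESS in
the hundreds). Convergence failure flags the result
(`converged = FALSE`) rather than discarding it. When covariates are
constant within a nest, each interval's days share one design row, so
the likelihood collapses to one weighted row per interval — an exact
rewrite, not an approximation.

Nest success is Π S over the incubation period (27 days by default),
computed per posterior draw over a grass grid spanning the observed
covariate range (extrapolation warns, mirroring the convention of
plotting only over observed ranges); other covariates are held at their
means and year effects at zero. Because monitoring starts at incubation,
this quantity overstates success from initiation and is comparable only
under a shared convention — a reporting caveat, not a modelling choice.

## Pooled tests

The pooled analysis asks whether grass is taller at successful nests
*after accounting for phenology*. The mixed model uses **measured**
heights against **measurement day** with study×year random structure;
phenology is accounted for by the DAY term. Two structures are compared
by REML AICc: `(1 | stratum)` and `(day | stratum)` with unstructured
2 × 2 covariance. The fate effect is then tested by a likelihood-ratio
test on ML refits of the best structure (REML for structure, ML for
fixed-effect LRT — the conventional split). Corrected heights, which are
measurements *referenced to hatch date*, are paired with hatch day when
used in this layout (`pooled_data(use = "corrected")`); pairing them
with measurement day would mechanically re-introduce a fate offset,
because failed nests are corrected forward to a later date than they
were measured — an easy and consequential mistake this API prevents.

Mixed models are fit with lme4 (with nlme as an independent cross-check
in the tests); the best of two optimizers (bobyqa, nloptwrap) is kept,
because near-boundary random-slope fits can otherwise violate LRT
nesting. Singular fits are returned flagged, not suppressed.
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) counts fixed effects +
variance/covariance components + residual in k. Conditional R² is
deliberately not computed: it is a descriptive of particular datasets,
not part of the inferential chain.

The one-sided two-sample KS test uses D⁺ = sup[ECDF_failed −
ECDF_hatched], evaluated at pooled jump points (ties need no
randomization). The p-value is exp(−2D⁺²mn/(m+n)) asymptotically, with
exact label-permutation enumeration when m + n ≤ 20. The asymptotic tail
is anti-conservative at extreme small samples (at m = n = 1 it gives
0.37 where the exact answer is 0.5), which is why the exact branch
exists and is the default for small pooled samples.

## Numerical and experiment-size choices

* Interval likelihood in log space with `log1p`/`expm1` guards on both
  tails; enumeration agreement to 10⁻¹² (absolute, in log-likelihood).
* Noiseless simulations recover corrections to 10⁻¹⁰; un-correcting
  restores measured heights to 10⁻¹².
* Simulation experiments in the test suite use 12-stratum studies of
  ~500 nests with 50 replicates for coverage/bias experiments, 500
  replicates for LRT calibration, and 100 replicates per condition for
  AICc selection — sizes at which the Monte-Carlo bands asserted by the
  tests (e.g. ≥ 43/50 coverage for a nominal 95% interval) are
  comfortably informative.
* Stage seeds are split deterministically from one master seed
  (multiplicative-congruential step), so pipeline stages can be re-run
  independently and whole runs are byte-reproducible; CSV output uses
  17 significant digits so file-mode re-analysis is bit-identical.

## Known limitations

* The simulator's linear-growth assumption matches the correction's
  model; real seasons curve and senesce, and the correction inherits
  whatever lack of fit the per-stratum line has.
* Phenology-slope uncertainty is not propagated (plug-in), slightly
  understating downstream uncertainty in small strata.
* Binary fate only; abandonment, censoring, and re-nesting are out of
  scope.
* The year "random effect" in the survival model uses one fixed
  hyperprior scale (half-Normal(0, 5)); with very few years the
  hyperparameter is weakly identified.
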