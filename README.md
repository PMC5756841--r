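# nestpheno

Phenology-corrected vegetation covariates and Bayesian daily
nest-survival inference for ground-nesting birds.

## The problem

Field studies of ground-nesting birds (the motivating system is greater
sage-grouse) routinely measure the vegetation around each nest — e.g.
mean grass height from replicated transect samples — and relate it to
nest survival to test the *nest concealment hypothesis*. A pervasive
protocol measures vegetation on the day a nest's **fate** is discovered.
Because successful nests persist through the full incubation period
while failed nests drop out early, successful nests are measured later
in the season, on average. Where grass grows within the season, this
timing difference alone makes grass look taller at successful nests:
phenology masquerades as concealment.

`nestpheno` implements the complete inference chain around this bias,
for simulated studies with known truth:

1. **Simulation** (`sim_config()`, `simulate_study()`) — multi-site,
   multi-year nest studies with stratum-specific linear grass growth,
   daily Bernoulli nest survival, periodic nest visits, and a
   configurable measurement protocol (`FATE_DATE`, `HATCH_DATE`,
   `SCHEDULED`).
2. **Phenology correction** (`fit_phenology()`, `correct_heights()`) —
   per study-area × year stratum, an OLS regression of measured height
   on measurement day estimates the growth rate β_grass (cm/day), and
   each nest's height is standardized to its predicted hatch date:

   ```
   GrassHeight_hatch = GrassHeight_fate − (SurveyDate_fate − SurveyDate_hatch) × β_grass
   ```

3. **Daily nest survival** (`fit_survival()`, `success_curve()`) — the
   Bayesian logit-linear daily survival model

   ```
   y[i,t] ~ Bernoulli(y[i,t−1] · S[i,t]),   logit(S[i,t]) = β0 + x[i]'β
   ```

   fit with an exact interval-censored likelihood: for an inter-visit
   interval, the contribution is Π S_t if the nest survived and
   1 − Π S_t if it was found failed (the exact marginal over the
   unobserved failure day, since failure is absorbing). Coefficients get
   vague Normal(0, σ = 1000) priors; sampling is adaptive random-walk
   Metropolis (compiled, with an R reference implementation,
   `run_mcmc()`). Nest success is the product of daily survival over the
   27-day incubation period, reported with 95% credible bands over the
   observed grass-height range.
4. **Pooled tests** (`fit_lmm()`, `aicc()`, `lrt_fate()`,
   `ks_one_sided()`) — linear mixed models of height vs. day with
   `(1 | site:year)` or `(day | site:year)` random structures compared
   by AICc; a 1-df likelihood-ratio test for a nest-fate effect after
   accounting for phenology; and a one-sided two-sample
   Kolmogorov–Smirnov test (exact label-permutation p for pooled
   samples ≤ 20) of whether corrected heights at hatched nests are
   stochastically larger.
5. **Pipeline** (`run_pipeline()`, `plot_success_curves()`) — the whole
   chain with per-stage CSV outputs, a versioned `report.json`, full
   seed control, and a dotted-vs-solid success-curve contrast figure.
   A thin command-line front end lives at
   `inst/scripts/nestpheno-pipeline.R`
   (subcommands `simulate`, `correct`, `fit-survival`, `pooled-tests`,
   `run-all`, `plot`).

## Worked example

Simulate a 12-stratum study (504 nests) under the biased fate-date
protocol with **no true effect** of grass on survival, then run the full
analysis:

```r
library(nestpheno)
cfg <- sim_config(n_sites = 4, n_years = 3, nests_per_stratum = 42,
                  seed = 1)                       # FATE_DATE, effect = 0
report <- run_pipeline(cfg,
                       control = mcmc_control(chains = 3, iter = 2000,
                                              warmup = 1000, seed = 1),
                       seed = 1)
print(report)
#> <run_report>
#>   504 nests (215 hatched); corrections: mean 2.40 cm, mean |.| 2.40 cm (SD 3.10)
#>   grass coefficient (per cm): uncorrected 0.087 [0.067, 0.106]; corrected 0.002 [-0.017, 0.022]
#>   phenology structure by AICc: random slope (dAICc 39.80)
#>   LRT fate: chi2 = 0.226, df = 1, p = 0.634; KS one-sided p = 0.565
#>   median corrected height: 20.02 cm (hatched) vs 19.98 cm (failed)
```

Read: although grass height has **zero** effect on survival here, the
uncorrected analysis reports a strongly "significant" coefficient of
0.087 per cm (95% CrI excluding zero) — purely an artifact of
measurement timing. After correcting heights to hatch date the
coefficient collapses to 0.002 with a CrI straddling zero, the
likelihood-ratio test for a fate effect is null (p = 0.63), the
one-sided KS test is null (p = 0.57), and median corrected heights at
hatched and failed nests agree to within 0.05 cm.
`plot_success_curves(report)` draws the corresponding nest-success
curves (dotted = biased, solid = corrected).

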