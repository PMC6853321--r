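# pooltrend

Two-stage trend analysis of organochlorine pesticide (OCP) concentrations
measured in pooled human serum.

## The problem

Persistent organochlorine pesticides (HCB, β-HCH, trans-nonachlor,
p,p'-DDE, p,p'-DDT) accumulate in human tissue for decades after their
agricultural use ended.  Biomonitoring programmes track them in *pooled*
serum: one measurement (ng/g lipid) per pool of individuals who share an
age group, gender and collection period.  The resulting data form a small,
unbalanced three-way categorical design, and the questions of interest are
interactions — do age-specific trends diverge over time, and do genders
differ within an age group?

`pooltrend` is for biostatisticians and exposure scientists analysing such
pooled-biomonitoring series.  It implements a two-stage analysis:

1. **Screening** — stagewise least-squares boosted regression trees over
   the three categorical predictors, with relative variable importance
   (rescaled to sum to 100), pairwise interaction strength (the residual
   variance of an additive linear model fitted to grid predictions) and
   partial-dependence marginal effects.

2. **Inference** — three Bayesian hierarchical models for the pooled log
   concentration `y[a,g,t]`, estimated by a conjugate Gibbs sampler:

   * Model 1 (age × time): `y ~ N(beta[a,t], sigma²)` with a random walk
     `beta[a,t] ~ N(beta[a,t−1], omega²)`, `beta[a,0] ~ N(0, omega²)`;
   * Model 2 (age × gender): `y ~ N(alpha[a,g], sigma²)`,
     `alpha[a,g] ~ N(delta_a[a], phi²)`;
   * Model 3 (both): `y ~ N(alpha[a,g] + beta[a,t], sigma²)`,
     `alpha[a,g] ~ N(delta_g[g], phi²)`;

   with Normal(0, 10000) priors on top-level means and Uniform(0, 100)
   priors on the standard deviations.  Fits are assessed by posterior
   predictive-interval coverage (80/90/95%), DIC (`D(θ*) + 2 p_D`) and
   RMSE, and summarised as posterior trajectories, percent changes between
   collection periods (`100 · (exp(m₂ − m₁) − 1)` per draw), cohort
   extrapolations and a subsampling sensitivity check.

A synthetic-data generator reproduces the study's sampling design (154
pools over 5 ages × 2 genders × 5 periods, 2002/03–2012/13, with the
oversampled 5-15 cell in 2006/07) so the whole pipeline is testable without
any external data.  See `vignettes/pooltrend-methods.Rmd` for the full
model description and design decisions.

## Worked example

```r
library(pooltrend)

# a synthetic β-HCH-like series at the study design: diverging age trends
# (random walk, omega = 0.25) plus an age-by-gender level (phi = 0.3)
p <- hier_params(3, sigma = 0.3, omega = 0.25,
                 beta0 = c(4, 3.5, 3, 2.8, 2.5),
                 delta_g = c(0.3, -0.3), phi = 0.3)
serum <- simulate_pools(default_design(), p, seed = 2026, ocp = "beta-HCH")

# stage one: which predictors and interactions matter?
brt <- fit_brt(serum, shrinkage = 0.05, max_trees = 1000, split_seed = 1)
round(relative_importance(brt), 1)
#> age_group    gender    period
#>      48.4      43.2       8.4
signif(interaction_table(brt), 3)
#> age_group:gender age_group:period    gender:period
#>          0.01310          0.01030          0.00352

# stage two: fit the model matching the screened interactions
fit <- fit_hier(serum, model = 3, iter = 3000, burnin = 3000, seed = 1)
assess(fit)
#> Model 3 assessment
#>   PI coverage: 80%: 88.96%, 90%: 94.16%, 95%: 97.40%
#>   DIC 80.12 (p_d 25.74, mean deviance 54.38)
#>   RMSE 0.263; sigma 0.29 (0.257, 0.33)
max(gelman_rubin(fit)$psrf)
#> [1] 1.003

percent_change(fit, "46-60", "2002/03", "2012/13")
#>   age_group        comparison percent_change       lwr      upr
#> 1     46-60 2002/03 → 2012/13      -21.71275 -44.80837 8.631998
```

Age group and gender dominate the screening (the generating model has both
interaction blocks), the ensemble ranks the two age interactions well above
gender × period, and the hierarchical fit recovers the observation noise
(posterior σ 0.29 against a generative 0.3) with chains that pass the
Gelman–Rubin threshold.  The percent-change summary says concentrations for
46-60 year olds fell by about 22% over the decade, with a 95% credible
interval wide enough to include no change — the pattern expected from 154
pools.

`run_pipeline()` (or the `inst/cli/pooltrend.R` script) chains all stages —
simulate/read → screen → fit → assess → report — and writes tab-separated
tables plus a JSON manifest.

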