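# planktrend

Hierarchical Bayesian trend analysis of diatom and dinoflagellate carbon
biomass from semi-quantitative plankton survey records.

## The problem

Multi-decadal plankton surveys (the Continuous Plankton Recorder being the
archetype) count taxa along ship tracks. Two questions matter for how a
warming ocean restructures phytoplankton communities: how the carbon biomass
of the diatom and dinoflagellate functional groups has trended over decades,
and whether the community composition — the **diatom index**
`p = q / (q + r)`, the diatom share of combined diatom (`q`) and
dinoflagellate (`r`) biomass — has shifted. `planktrend` implements the full
chain from taxon counts to posterior trend estimates:

1. **Carbon conversion** — allometric power laws `log10(pg C) = a + b log10(V)`
   per group (diatom `a = -0.541, b = 0.811`; general protist
   `a = -0.665, b = 0.939` for dinoflagellates), with geometric-mean carbon
   imputation for taxa of unknown size.
2. **Aggregation** — province × 2.5° latitude band × month × year bins;
   zeros of each group replaced by 50% of that group's minimum positive
   binned biomass (half-detection-limit imputation); the index analyzed on
   the logit scale `h = ln(p / (1 - p))`.
3. **SST anomaly** — a Bayesian decomposition
   `SST = alpha[m,A] + rho_A (l - lbar_A) + beta_A (y - 1960) + sst` whose
   residual posterior median is a temperature covariate orthogonal to month,
   latitude, province and year (a least-squares fast mode is provided).
4. **Trend models** — for each response (`ln q`, `ln r`, `ln(q+r)`, `h`),
   the Time-Space-Temperature model
   `mu = theta[m,A] + eta_A (l - lbar_A) + gamma_A (y - 1960) + phi_A sst`
   or the Time-Space model with decade steps `delta[d,A]` under an Extended
   Bayesian LASSO prior (`delta ~ N(0, s2_A)`, `s2_A ~ Exp(lambda_A^2 / 2)`,
   `lambda_A = lambda xi_A`, `lambda ~ Gamma(1,1)`, `xi_A ~ Uniform(0,2)`),
   fit by a blocked Gibbs sampler with exchangeable Normal effect priors,
   InvGamma(0.1, 0.1) hyper-variances and Uniform(0, 10) residual sds.
5. **Diagnostics & reporting** — posterior predictive checks with Bayesian
   p-values, draws-based Bayesian R², leave-one-predictor-out variable
   importance, and trend tables in % per year
   (`100 (e^gamma - 1)`) and compounded multi-decade change
   (`100 ((1 + rate/100)^years - 1)`).

A synthetic-data generator emulating the survey's structure (seasonal
cycles, latitudinal gradients, linear trends, anomaly effects, excess zeros)
makes every stage testable without any data download; generative ground
truth is recorded and recovered in the tests.

## Worked example

```r
library(planktrend)

study <- simulate_study(years = 1960:2017, seed = 42,
                        n_diatoms = 10, n_dinos = 10)
bins  <- prepare_bins(study$abundance, study$traits)
anom  <- sst_anomaly(study$sst, mode = "fast")

cfg <- model_config("logit_index", "tst", chains = 2, iterations = 1500,
                    burnin = 500, thin = 2, seed = 42)
fit <- fit_trend_model(bins, anom, cfg)
fit
#> Hierarchical trend model fit
#>   response: logit_index  variant: tst
#>   provinces: ARCT, NADR, NECS, NWCS, SARC
#>   draws: 1000 retained over 2 chains
#>   converged: TRUE (max split-Rhat 1.008)

trend_report(fit)[, c("province", "slope", "pct_per_yr", "compounded_pct")]
#>   province    slope pct_per_yr compounded_pct
#> 1     ARCT -0.00510     -0.509          -26.4
#> 2     NADR  0.00945      0.950           76.3
#> 3     NECS  0.02940      2.983          483.5
#> 4     NWCS  0.01405      1.415          132.4
#> 5     SARC  0.00750      0.753           56.8
```

The simulated study contained 13,712 bins (4.9% diatom-zero, 23.4%
dinoflagellate-zero before imputation). The `slope` column is the posterior
median interannual trend of the logit diatom index per province;
`pct_per_yr` converts it exactly (`100 (e^slope - 1)`), so e.g. NADR's
+0.95%/yr means the odds of a unit of biomass being diatom rather than
dinoflagellate grew about 1% per year; `compounded_pct` compounds that rate
over 60 years. The generator's true index trends were ARCT −0.009,
SARC +0.010, NADR +0.007, NWCS +0.015, NECS +0.025 per year — each inside
the fitted 95% credible interval.

Other entry points: `fit_sst_model()` / `compute_anomaly()`,
`posterior_predictive_check()`, `bayesian_r2()`, `variable_importance()`,
`monthly_climatology()`, `slope_summary()`, and the on-disk pipeline stages
`pipeline_simulate()` → `pipeline_prepare()` → `pipeline_fit()` →
`pipeline_check()` → `pipeline_report()` (thin CLI wrapper in
`inst/scripts/pipeline.R`).

## Bin table columns

`prepare_bins()` / `bins.csv`: `province`, `latitude` (band center, °N),
`year`, `month`, `decade`, `q` and `r` (binned diatom / dinoflagellate
biomass, µg C, post-imputation), `q_imputed`, `r_imputed` (flags),
`p` (diatom index), `h` (logit index).
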