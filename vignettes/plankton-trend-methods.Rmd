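---
title: "Methods: hierarchical Bayesian trends in plankton functional-group biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian trends in plankton functional-group biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Semi-quantitative plankton surveys such as the Continuous Plankton Recorder
(CPR) record taxon-level abundance counts along ship tracks over decades.
Two questions drive this package: how has the carbon biomass of the diatom
and dinoflagellate functional groups changed over a multi-decade record, and
has the *composition* of that community — summarized by the diatom index
`p = q / (q + r)`, the diatom share of combined diatom (`q`) plus
dinoflagellate (`r`) biomass — shifted? Because `(p, 1 - p)` is
compositional, the index is analyzed on the logit scale,
`h = logit(p) = ln(p / (1 - p))`, where conventional Gaussian machinery
applies.

## From counts to biomass bins

1. **Carbon conversion.** Each taxon's mean cell volume `V` (µm³) is
   converted to cell carbon by a group-specific power law
   `log10(pg C) = a + b log10(V)` (defaults: diatoms `a = -0.541,
   b = 0.811`; the general protist relation `a = -0.665, b = 0.939` for
   dinoflagellates). The coefficients are configuration, not code
   (`carbon_coefficients()`), because different allometric calibrations
   exist. A taxon with unknown volume receives the geometric mean of the
   per-cell carbon of its group — imputation on the carbon scale, since the
   quantity that enters the analysis is carbon. Community biomass of a
   sample is the abundance-weighted sum of per-cell carbon over taxa, in
   µg C throughout (report tables may rescale).
2. **Binning.** Samples are aggregated into province × 2.5°-latitude-band ×
   month × year bins; longitude is discarded inside a province. Bands are
   half-open intervals `[k·w, (k+1)·w)` anchored at the equator, identified
   by their midpoint — the anchoring convention is ours (only the width is
   externally given); it is reproducible and coordinate-free.
3. **Zero imputation.** A bin with zero biomass for one group cannot enter
   a logit or log analysis. Zeros of each group are replaced independently
   by 50% of the minimum positive binned biomass of that group over the
   whole aggregated dataset — a half-detection-limit rule computed once
   globally, not per province. Imputed bins are flagged. The index `p` and
   its logit `h` are computed after imputation, so both are always finite.

`p` and `h` are invariant to a common rescaling of all biomasses, which is
why the index is robust to slow changes in sampled water volume (ship speed)
that affect both groups equally.

## The models

All responses (`ln q`, `ln r`, `ln(q + r)`, `h`) use the same hierarchical
Gaussian structure within province `A`:

**Time-Space-Temperature (TST):**
`mu = theta[m, A] + eta[A] (l - lbar[A]) + gamma[A] (y - 1960) + phi[A] sst[A,l,m,y]`

**Time-Space (TS):**
`mu = theta[m, A] + eta[A] (l - lbar[A]) + gamma[A] (y - 1960) + delta[d, A]`

with `y ~ Normal(mu, sigma[A]^2)`. `theta` are twelve month effects (there
is no global intercept: `theta` absorbs province-level means, and
identifiability of the remaining terms comes from the hierarchical priors,
not sum-to-zero constraints), `eta` a latitudinal gradient per degree,
`gamma` the interannual trend per year, `phi` the effect of the SST anomaly
per °C, and `delta` a step per calendar decade (1960, 1970, …).
`lbar[A]` is the mean latitude of the observations in province `A` (the
observed-data mean, not a geometric province centroid — the data are the
only latitude information the model sees).

Priors: exchangeable `N(0, sigma_class^2)` on each effect class across
provinces, with `InvGamma(0.1, 0.1)` hyper-priors on the class variances;
`Uniform(0, 10)` on each `sigma[A]`. The decade steps get the Extended
Bayesian LASSO prior: `delta[d, A] ~ N(0, s2[A])`,
`s2[A] ~ Exp(rate = lambda[A]^2 / 2)` — note the *rate* parameterization,
so `E[s2[A]] = 2 / lambda[A]^2`; textbook Bayesian-LASSO conventions
differ — with `lambda[A] = lambda * xi[A]`, `lambda ~ Gamma(1, 1)`,
`xi[A] ~ Uniform(0, 2)`. The LASSO selectively shrinks irrelevant decade
steps toward zero while letting a genuine step escape.

### The SST anomaly

SST covaries with month, latitude, province and year — exactly the
predictors already in the model. To avoid collinear predictors, observed
SST is decomposed by the same hierarchical structure
(`alpha[m, A] + rho[A](l - lbar[A]) + beta[A](y - 1960) + residual`), and
the *anomaly* is the posterior median of the residual per record. By
construction it is empirically orthogonal to month, latitude and year,
so adding it to the TST model leaves the other posteriors essentially
unchanged while absorbing residual variance. A deterministic fast mode
(per-province least-squares residuals) is provided alongside the Bayesian
mode; with these diffuse priors and data sizes they agree to well under
0.05 °C RMS, and the Bayesian mode is the default.

## Computation

The joint posterior has no closed form. We use a blocked Gibbs sampler:
per-province coefficient blocks are conjugate multivariate normal (sampled
via Cholesky of the 14–20 dimensional posterior precision), province
variances are truncated inverse gamma (the flat prior is on `sigma`, not
`sigma^2`), class hyper-variances are conjugate inverse gamma, and the
LASSO scales (`s2[A]`, `lambda`, `xi[A]`) are updated by univariate slice
sampling. Sufficient statistics (`X'X`, `X'y`, `y'y`) are precomputed per
province, so an iteration's cost is independent of the number of
observations.

The default protocol (3 chains × 10,000 iterations, 4,000 burn-in, thinned
by 10) mirrors the classic WinBUGS/OpenBUGS-era prescription. The blocked
sampler mixes far better than single-site updating, so the tests and the
acceptance script run 1–2 chains of roughly 1,000–1,200 iterations with
short burn-in, which gives effective sample sizes in the hundreds on these
problems. Convergence is assessed quantitatively — split-chain potential
scale reduction < 1.05 and effective sample size > 100 for every parameter —
rather than by eyeballing traceplots; a fit that misses the thresholds is
returned with `converged = FALSE` and a warning, never silently.

**A numerical subtlety worth knowing.** Because the model has no global
intercept, a constant can trade between the twelve month effects and the
decade steps of a province (and, through the staircase shape of the decade
indicators, partially against the linear trend). The posterior along this
ridge is only weakly identified by the heavy-tailed hyper-priors. The
shrinkage basin — level in `theta`, `delta` near zero — is the
scientifically meaningful one, and the sampler starts there: initial
coefficients come from least squares on the non-decade columns, decade
steps start at zero, and the LASSO scale starts small. Flat priors on
`delta` would remove the shrinkage that resolves this near-collinearity;
do not replace the LASSO layer with them.

## Diagnostics

* **Posterior predictive checks.** 100 replicate datasets are simulated at
  the observed design points, each from one retained posterior draw; the
  Bayesian p-value is `P(T_rep >= T_obs)` for `T` the mean or variance,
  pooled by default (per-province optional). Values near 0 or 1 flag
  misfit; 0.25–0.75 is the conventional comfortable band. Under a
  well-specified model the p-values concentrate near 0.5; inflating the
  observed variance fourfold drives the variance p-value to ~0.
* **Bayesian R².** The name is used in the literature without a formula;
  we adopt the draws-based definition: per retained draw,
  `R2 = var(mu) / (var(mu) + mean(sigma[A(i)]^2))`, summarized by the
  posterior median. It includes between-province differences absorbed by
  `theta` as explained variance.
* **Variable importance.** Leave-one-predictor-out refits with the same
  MCMC protocol; `delta_R2 = R2(full) - R2(without)`. Omitting the month
  effects substitutes a single province intercept, otherwise the model
  would lose all level information and the comparison would be meaningless;
  omitting latitude or the anomaly just drops the term.

## The synthetic-data generator

Because the real survey archives cannot ship with a package, a generator
produces data with the same structure the models assume:

* a taxon trait table with log-normal cell volumes (diatom median 10³ µm³,
  dinoflagellate median 10⁴ µm³, sdlog 1), optionally with one unknown-size
  taxon per group to exercise the imputation rule;
* an SST grid over five provinces (categorical labels with latitude spans
  mimicking ARCT, SARC, NADR, NWCS, NECS; four 2.5° bands each) built from
  the same decomposition the SST model fits, retaining the realized
  residual as the true anomaly;
* abundance records: per cell and group, log biomass is drawn from the TST
  mean structure plus noise, suppressed entirely with a per-province
  zero-inflation probability, and otherwise partitioned across the group's
  taxa by symmetric Dirichlet(1) weights (the real within-group abundance
  distribution is unknown; Dirichlet(1) is the maximally uninformative
  stand-in) and divided by per-cell carbon.

Each group's log biomass follows its own mean structure; the defaults set
the logit-index block exactly equal to the diatom-minus-dinoflagellate
differences, so all three responses are mutually consistent and the index
inherits `sigma_h = sqrt(2) * 0.75 ≈ 1.06` from the two group noises.
Default trends follow the observed province pattern (diatom biomass
declining in the north, rising on the shelves; index rising everywhere
except the Arctic), anomaly effects are positive for both biomasses and
negative for the index (near zero in NWCS), latitude effects are weak
(~1–2% of variance), and zero-inflation probabilities are solved so that
about 5% of observed bins are diatom-zero and 24% dinoflagellate-zero, with
roughly 45% of the dinoflagellate zeros in the two northern provinces.

`simulate_bins()` bypasses the abundance stage and draws bin-level
responses directly from the mean structure — the fitted model is then
exactly the generative model, which is what parameter-recovery,
posterior-predictive-calibration and R² studies require.

**What the generator does not emulate.** Sampling effort is uniform (one
sample per cell), so binned biomass has a much narrower distribution than
real survey bins, which aggregate wildly varying numbers of samples. One
consequence: the global half-minimum imputation floor sits several standard
deviations below a typical bin, so imputed-zero bins are pronounced
logit-index outliers here — the same spike phenomenon real imputed data
show, but sharper. The normality property of `h` is therefore asserted on
the non-imputed bins (where it holds exactly by construction) together
with a bounded-skewness check on the full set; a formal normality test on
~24%-contaminated data rejects at any realistic sample size even when the
distribution is visually "approximately normal". Ship-track geometry,
effort drift over time, and presence-only records are likewise out of
scope.

## Reporting

Slopes on the log/logit scale convert to percent change per year by the
exact formula `100 (e^slope - 1)` (a slope of 0.01 a⁻¹ is approximately a
1% change per year; we keep the exact form and note the approximation).
Annual rates compound over a horizon as `100 ((1 + rate/100)^years - 1)`:
+1%/yr ≈ +82% and +2%/yr ≈ +228% over the default 60-year horizon; −1%/yr
and −2%/yr compound to ≈ −45% and −70%. Credible-interval bounds are passed
through the same transforms. Monthly climatologies report the twelve
month-effect posteriors per province with the annual mean as the mean of
the twelve medians.

## Problem sizes and test design

The test suite and the acceptance script size their simulations so the
whole run stays comfortable on a single CPU: recovery studies use
5 provinces × 4 bands × 12 months × 40 years (9,600 bins) with 1–2 chains
of ~1,200 iterations; LASSO checks use the full 1960–2017 span (6 decades);
the SST orthogonality check uses ~5,000 records. At these sizes the
interannual trend is estimated to ±0.005 and 95% credible intervals attain
close to nominal coverage (≈95% across 1,600 parameter checks). An
independent cross-check fits the identical model with JAGS on a small
fixture and matches posterior means and standard deviations within Monte
Carlo error.

## Known limitations

* Provinces are categorical labels; there is no polygon geometry, no
  spatial random field, and no ice masking for high-latitude SST.
* Trends are linear in year by design; the decade steps and the anomaly
  term are the only non-linearities considered.
* The generator's equal-effort bins overstate the sharpness of the
  imputation spike (see above), and real surveys' taxonomic drift,
  presence-only records and volume changes are not modelled.
* The month-vs-decade level ridge means TS-variant posteriors for
  individual `theta` levels and `delta` steps should be interpreted
  jointly, not marginally, if the LASSO layer is weakened.
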