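# Cross-validation of the blocked Gibbs sampler against an independent MCMC
# engine (JAGS) on a small fixture, plus prior-predictive checks.

test_that("Gibbs posterior agrees with JAGS on the same hierarchical model", {
  library(rjags)
  p <- tiny_params(trend = c(0.02, -0.01), lat = c(0.1, 0.05),
                   anom = c(-0.1, -0.2), sigma = c(0.3, 0.3))
  sim <- simulate_bins(p, "log_diatom", years = 1990:1999, seed = 101)
  bins <- sim$bins
  fit <- fit_trend_model(bins, sim$anomalies,
                         model_config("y", "tst", chains = 2,
                                      iterations = 3000, burnin = 500,
                                      thin = 1, seed = 11))
  dm <- do.call(rbind, lapply(fit$draws, as.matrix))

  provs <- sort(unique(bins$province))
  lbar <- tapply(bins$latitude, bins$province, mean)
  anom <- sim$anomalies$anomaly
  jm <- "
  model {
    for (i in 1:N) {
      mu[i] <- theta[prov[i], month[i]] + eta[prov[i]] * latdev[i] +
               gamma[prov[i]] * yr[i] + phi[prov[i]] * an[i]
      y[i] ~ dnorm(mu[i], tau.eps[prov[i]])
    }
    for (a in 1:P) {
      for (m in 1:12) { theta[a, m] ~ dnorm(0, tau.theta) }
      eta[a] ~ dnorm(0, tau.eta)
      gamma[a] ~ dnorm(0, tau.gamma)
      phi[a] ~ dnorm(0, tau.phi)
      sigma[a] ~ dunif(0, 10)
      tau.eps[a] <- 1 / (sigma[a] * sigma[a])
    }
    tau.theta ~ dgamma(0.1, 0.1)
    tau.eta ~ dgamma(0.1, 0.1)
    tau.gamma ~ dgamma(0.1, 0.1)
    tau.phi ~ dgamma(0.1, 0.1)
  }"
  dat <- list(
    N = nrow(bins), P = length(provs),
    y = bins$y, month = bins$month,
    prov = match(bins$province, provs),
    latdev = bins$latitude - lbar[bins$province],
    yr = bins$year - 1960, an = anom
  )
  set.seed(11)
  jags <- jags.model(textConnection(jm), data = dat, n.chains = 2,
                     n.adapt = 500, quiet = TRUE)
  js <- coda.samples(jags, c("theta", "eta", "gamma", "phi", "sigma"),
                     n.iter = 3000)
  jmat <- do.call(rbind, lapply(js, as.matrix))

  for (a in seq_along(provs)) {
    A <- provs[a]
    expect_lt(abs(mean(dm[, paste0("gamma[", A, "]")]) -
                  mean(jmat[, paste0("gamma[", a, "]")])), 0.004)
    expect_lt(abs(mean(dm[, paste0("eta[", A, "]")]) -
                  mean(jmat[, paste0("eta[", a, "]")])), 0.02)
    expect_lt(abs(mean(dm[, paste0("phi[", A, "]")]) -
                  mean(jmat[, paste0("phi[", a, "]")])), 0.03)
    expect_lt(abs(mean(dm[, paste0("sigma[", A, "]")]) -
                  mean(jmat[, paste0("sigma[", a, "]")])), 0.02)
    # month-effect levels trade off slowly against the uncentered year trend
    # in JAGS's single-site sampler, so compare levels at a tolerance set by
    # that MC error and month CONTRASTS (which mix fast in both) tightly
    th_mine <- colMeans(dm[, sprintf("theta[%s,%d]", A, 1:12)])
    th_jags <- colMeans(jmat[, sprintf("theta[%d,%d]", a, 1:12)])
    expect_lt(max(abs(th_mine - th_jags)), 0.12)
    expect_lt(max(abs((th_mine - mean(th_mine)) - (th_jags - mean(th_jags)))),
              0.03)
  }
})

test_that("with no data the sampler reproduces the prior marginals", {
  design <- planktrend:::build_design(
    data.frame(province = character(0), latitude = numeric(0),
               year = integer(0), month = integer(0)),
    numeric(0),
    terms = c("month", "lat", "trend", "decade"),
    lbar = c(X = 50), provinces = "X", decades = c(1960, 1970)
  )
  cfg <- model_config("y", "ts", chains = 1, iterations = 26000,
                      burnin = 1000, thin = 25, seed = 5)
  draws <- planktrend:::run_gibbs(design, cfg)
  m <- as.matrix(draws[[1]])

  # sigma ~ Uniform(0, 10): with no data it is drawn fresh each iteration
  ks_sig <- stats::ks.test(m[, "sigma[X]"], "punif", 0, 10)
  expect_gt(ks_sig$p.value, 0.01)

  # xi ~ Uniform(0, 2) marginally
  ks_xi <- stats::ks.test(m[, "xi[X]"], "punif", 0, 2)
  expect_gt(ks_xi$p.value, 0.01)

  # gamma marginal: scale mixture of normals with InvGamma(0.1, 0.1)
  # variance, i.e. a scaled Student t with 0.2 degrees of freedom
  ks_g <- stats::ks.test(m[, "gamma[X]"] / sqrt(0.1 / 0.1), stats::pt, df = 0.2)
  expect_gt(ks_g$p.value, 0.01)
})

test_that("chains pass split-Rhat and effective-size thresholds on clean data", {
  p <- tiny_params(sigma = c(0.4, 0.4))
  sim <- simulate_bins(p, "logit_index", years = 1980:1999, seed = 107)
  fit <- fit_trend_model(sim$bins, sim$anomalies, fast_config(seed = 107))
  expect_true(fit$converged)
  expect_lt(max(fit$convergence$rhat), 1.05)
  expect_gt(min(fit$convergence$ess), 100)
})
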