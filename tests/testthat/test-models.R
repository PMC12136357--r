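test_that("linear predictor evaluates the additive mean structure exactly", {
  pars <- list(A = list(theta = rep(1, 12), eta = 0.1, gamma = 0.01,
                        lbar = 50, phi = 0,
                        delta = c(`1970` = 0)))
  bin <- list(province = "A", latitude = 52.5, month = 3, year = 1970)
  expect_equal(linear_predictor(pars, bin, anomaly = 0), 1.35)

  zero <- list(A = list(theta = rep(0, 12), eta = 0, gamma = 0, lbar = 50,
                        phi = 0, delta = c(`1970` = 0)))
  expect_equal(linear_predictor(zero, bin, anomaly = 1.3), 0)
  expect_equal(linear_predictor(zero, bin, variant = "ts"), 0)

  # ts with zero decade step equals tst with zero anomaly effect
  expect_equal(linear_predictor(pars, bin, anomaly = 2.2),
               linear_predictor(pars, bin, variant = "ts") + 0 * 2.2 + 0.0)
  expect_error(linear_predictor(pars, bin), "anomaly")
  expect_error(linear_predictor(pars, list(province = "B", latitude = 50,
                                           month = 1, year = 1970), 0),
               "unknown province")
})

test_that("interannual trends are recovered with credible intervals covering truth", {
  p <- tiny_params(trend = c(0.02, -0.01), sigma = c(0.3, 0.3))
  sim <- simulate_bins(p, "log_diatom", years = 1960:1999, seed = 17)
  fit <- fit_trend_model(sim$bins, sim$anomalies, fast_config(seed = 17))
  s <- slope_summary(fit, "gamma")
  truth <- p$responses$log_diatom$trend[match(s$province, p$provinces$province)]
  expect_true(all(s$q2.5 <= truth & truth <= s$q97.5))
  expect_true(all(abs(s$q50 - truth) < 0.005))
})

test_that("anomaly effect is recovered on the logit index", {
  p <- tiny_params(anom = c(-0.10, -0.10), sigma = c(0.5, 0.5))
  sim <- simulate_bins(p, "logit_index", years = 1980:2009, seed = 23)
  expect_gt(nrow(sim$bins), 2000)
  fit <- fit_trend_model(sim$bins, sim$anomalies, fast_config(seed = 23))
  s <- slope_summary(fit, "phi")
  expect_true(all(s$q50 > -0.15 & s$q50 < -0.05))
})

test_that("time-space and time-space-temperature fits agree on shared effects", {
  p <- tiny_params(sigma = c(0.4, 0.4))
  sim <- simulate_bins(p, "logit_index", years = 1965:2004, seed = 29)
  f_tst <- fit_trend_model(sim$bins, sim$anomalies, fast_config(seed = 29))
  # short chains: the slow-mixing LASSO scale can miss the ESS threshold,
  # which the fit reports as a warning; gamma/eta mix well regardless
  f_ts <- suppressWarnings(
    fit_trend_model(sim$bins, NULL, fast_config(variant = "ts", seed = 29))
  )
  for (par in c("gamma", "eta")) {
    a <- slope_summary(f_tst, par)
    b <- slope_summary(f_ts, par)
    # overlapping 95% intervals province by province
    expect_true(all(pmax(a$q2.5, b$q2.5) <= pmin(a$q97.5, b$q97.5)))
  }
  # anomaly carries information: trend uncertainty no wider under tst
  wa <- with(slope_summary(f_tst, "gamma"), q97.5 - q2.5)
  wb <- with(slope_summary(f_ts, "gamma"), q97.5 - q2.5)
  expect_lt(mean(wa), mean(wb) * 1.1)
})

test_that("LASSO prior shrinks null decade effects and keeps a real step", {
  dec <- matrix(0, 2, 6)
  p0 <- tiny_params(sigma = c(0.3, 0.3), decade = dec)
  sim0 <- simulate_bins(p0, "log_diatom", years = 1960:2017, seed = 37)
  f0 <- fit_trend_model(sim0$bins, NULL, fast_config(variant = "ts", seed = 37))
  d0 <- slope_summary(f0, "delta")
  expect_gte(mean(d0$q2.5 <= 0 & 0 <= d0$q97.5), 0.95)

  dec1 <- dec; dec1[1, 3] <- 0.5   # one large step, 1980s, first province
  p1 <- tiny_params(sigma = c(0.3, 0.3), decade = dec1)
  sim1 <- simulate_bins(p1, "log_diatom", years = 1960:2017, seed = 41)
  f1 <- fit_trend_model(sim1$bins, NULL, fast_config(variant = "ts", seed = 41))
  d1 <- slope_summary(f1, "delta")
  spike <- d1[d1$province == "NORD" & d1$index == 1980, ]
  others <- d1[!(d1$province == "NORD" & d1$index == 1980), ]
  expect_gt(abs(spike$q50), 2 * max(abs(others$q50)))
})

test_that("slope summaries are exact quantiles with nested intervals", {
  p <- tiny_params(sigma = c(0.4, 0.4))
  sim <- simulate_bins(p, "log_dino", years = 1990:2001, seed = 43)
  fit <- fit_trend_model(sim$bins, sim$anomalies, quick_config(seed = 43))
  s <- slope_summary(fit)
  expect_true(all(s$q2.5 <= s$q17 & s$q17 <= s$q50 &
                  s$q50 <= s$q83 & s$q83 <= s$q97.5))
  dm <- do.call(rbind, lapply(fit$draws, as.matrix))
  g <- s[s$parameter == "gamma" & s$province == "NORD", ]
  expect_equal(g$q50, unname(stats::quantile(dm[, "gamma[NORD]"], 0.5)))
  expect_equal(g$q17, unname(stats::quantile(dm[, "gamma[NORD]"], 0.17)))
})

test_that("retained draw count follows the chains/iterations/burnin/thin protocol", {
  p <- tiny_params(sigma = c(0.4, 0.4))
  sim <- simulate_bins(p, "log_diatom", years = 1995:1999, seed = 47)
  cfg <- model_config("y", "tst", chains = 2, iterations = 600, burnin = 100,
                      thin = 5, seed = 3)
  fit <- fit_trend_model(sim$bins, sim$anomalies, cfg)
  expect_equal(coda::niter(fit$draws), (600 - 100) / 5)
  expect_equal(coda::nchain(fit$draws), 2)
  # xi draws respect their prior support under the ts variant
  cfg2 <- model_config("y", "ts", chains = 1, iterations = 300, burnin = 100,
                       thin = 1, seed = 3)
  fit2 <- suppressWarnings(fit_trend_model(sim$bins, NULL, cfg2))
  dm <- as.matrix(fit2$draws[[1]])
  expect_true(all(dm[, "xi[NORD]"] > 0 & dm[, "xi[NORD]"] < 2))
  expect_true(all(dm[, grep("^sigma", colnames(dm))] > 0))
})

test_that("model validation rejects malformed inputs", {
  p <- tiny_params()
  sim <- simulate_bins(p, "log_diatom", years = 1999:2000, seed = 53)
  expect_error(fit_trend_model(sim$bins[sim$bins$year == 1999, ], sim$anomalies,
                               quick_config()), "at least 2 years")
  expect_error(fit_trend_model(sim$bins, NULL, quick_config(variant = "tst")),
               "requires anomalies")
  bad <- sim$anomalies[-1, ]
  expect_error(fit_trend_model(sim$bins, bad, quick_config()), "no matching")
})
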