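test_that("taxon table generation: minimal case, determinism, volume law", {
  tt <- generate_taxon_table(1, 1, seed = 1)
  expect_equal(nrow(tt), 2)
  expect_true(all(tt$volume_um3 > 0))

  t1 <- generate_taxon_table(5, 5, seed = 7)
  t2 <- generate_taxon_table(5, 5, seed = 7)
  expect_identical(t1, t2)

  # group-wise geometric mean volume within a factor of 2 of the medians
  tt <- generate_taxon_table(50, 50, seed = 3)
  for (g in c("diatom", "dinoflagellate")) {
    v <- tt$volume_um3[tt$group == g]
    gm <- exp(mean(log(v), na.rm = TRUE))
    med <- c(diatom = 1e3, dinoflagellate = 1e4)[[g]]
    expect_gt(gm, med / 2)
    expect_lt(gm, med * 2)
  }
  expect_error(generate_taxon_table(0, 3, seed = 1), "counts")
})

test_that("simulated SST honours the additive decomposition exactly when noise-free", {
  p <- tiny_params(sst_sigma = c(0, 0), sst_trend = c(0.02, 0.02),
                   sst_lat = c(-0.5, -0.5))
  sst <- simulate_sst(p, years = c(1960, 2010), seed = 1)
  d <- sst[sst$province == "NORD" & sst$month == 6 & sst$latitude == sst$latitude[1], ]
  expect_equal(d$sst[d$year == 2010] - d$sst[d$year == 1960], 1.0)

  d2 <- sst[sst$province == "NORD" & sst$month == 6 & sst$year == 1960, ]
  d2 <- d2[order(d2$latitude), ]
  expect_equal(diff(d2$sst)[1], -0.5 * 2.5)
})

test_that("simulated SST residual noise has the configured scale", {
  p <- default_generative_params()   # sigma_sst = 1 degC in every province
  sst <- simulate_sst(p, years = 1960:2009, seed = 42)  # > 10,000 records
  expect_gt(nrow(sst), 10000)
  s <- stats::sd(sst$true_anomaly)
  expect_lt(abs(s - 1), 0.05)
  # detrended residuals from an independent per-province regression
  fitres <- unlist(lapply(split(sst, sst$province), function(d) {
    stats::residuals(stats::lm(sst ~ 0 + factor(month) + I(latitude - mean(latitude)) +
                                 I(year - 1960), data = d))
  }))
  expect_lt(abs(stats::sd(fitres) - 1), 0.05)
})

test_that("same seed reproduces the simulation; different seeds differ", {
  p <- tiny_params()
  a <- simulate_sst(p, years = 1990:1991, seed = 5)
  b <- simulate_sst(p, years = 1990:1991, seed = 5)
  d <- simulate_sst(p, years = 1990:1991, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$sst, d$sst)))
})

test_that("zero-inflation of one suppresses a group entirely", {
  p <- tiny_params(zero_r = c(1, 1))
  sst <- simulate_sst(p, years = 1990:1992, seed = 2)
  ab <- simulate_abundance(p, tiny_traits(), sst, seed = 3)
  expect_false("dinoflagellate" %in% ab$group)
  expect_true("diatom" %in% ab$group)
})

test_that("noise-free simulation round-trips through the pipeline exactly", {
  p <- tiny_params(sigma = c(0, 0), anom = c(0, 0))
  sst <- simulate_sst(p, years = 1995:1998, seed = 2)
  traits <- tiny_traits()[c(1, 3), ]  # one taxon per group
  ab <- simulate_abundance(p, traits, sst, seed = 3)
  bins <- prepare_bins(ab, traits)
  expect_false(any(bins$q_imputed | bins$r_imputed))

  pidx <- match(bins$province, p$provinces$province)
  lbar <- tapply(bins$latitude, bins$province, mean)[bins$province]
  r <- p$responses$log_diatom
  mu <- r$month[cbind(pidx, bins$month)] + r$lat[pidx] * (bins$latitude - lbar) +
    r$trend[pidx] * (bins$year - 1960)
  expect_equal(log(bins$q), as.numeric(mu), tolerance = 1e-10)
})

test_that("empirical zero fractions match the configured probabilities", {
  p <- tiny_params(zero_d = c(0.10, 0.10), zero_r = c(0.30, 0.30))
  sst <- simulate_sst(p, years = 1960:2009, seed = 8)
  ab <- simulate_abundance(p, tiny_traits(), sst, seed = 9)
  bins <- impute_zeros(aggregate_bins(community_biomass(ab, impute_missing_size(tiny_traits()))))
  # conditional on the bin being observed (not both groups zero)
  expect_lt(abs(mean(bins$q_imputed) - 0.10 * 0.70 / (1 - 0.03)), 0.02)
  expect_lt(abs(mean(bins$r_imputed) - 0.30 * 0.90 / (1 - 0.03)), 0.03)
})

test_that("default configuration reproduces the reported zero-bin rates", {
  st <- simulate_study(years = 1980:2009, seed = 11, n_diatoms = 5, n_dinos = 5)
  bins <- prepare_bins(st$abundance, st$traits)
  expect_lt(abs(mean(bins$q_imputed) - 0.05), 0.015)
  expect_lt(abs(mean(bins$r_imputed) - 0.24), 0.03)
  # dinoflagellate zeros concentrate in the two northern provinces
  north <- bins$province %in% c("ARCT", "SARC")
  expect_gt(sum(bins$r_imputed[north]) / sum(bins$r_imputed), 0.35)
})
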