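# Shared fixtures: small parameter sets and fast MCMC configs.

# two-province parameter set with controllable effects
tiny_params <- function(trend = c(0.02, -0.01), lat = c(0.1, 0.05),
                        anom = c(-0.1, -0.1), sigma = c(0.3, 0.3),
                        sst_trend = c(0.02, 0.02), sst_lat = c(-0.5, -0.5),
                        sst_sigma = c(1, 1), zero_d = c(0, 0),
                        zero_r = c(0, 0), month_amp = 1,
                        decade = NULL) {
  prov <- data.frame(province = c("NORD", "SUDE"),
                     lat_min = c(55, 45), lat_max = c(65, 55),
                     stringsAsFactors = FALSE)
  m <- 1:12
  # response-specific bloom timing shared by both provinces; provinces differ
  # by a level offset
  block <- function(k, peak) {
    month <- rbind(2 + month_amp * cos(2 * pi * (m - peak) / 12),
                   3 + month_amp * cos(2 * pi * (m - peak) / 12))
    list(month = month + k, lat = lat, trend = trend,
         anom = anom, sigma = sigma,
         decade = if (is.null(decade)) NULL else decade)
  }
  generative_params(
    prov,
    responses = list(log_diatom = block(6, peak = 5),
                     log_dino = block(6.5, peak = 7),
                     logit_index = block(-0.5, peak = 3)),
    sst = list(month = rbind(6 + 4 * cos(2 * pi * (m - 8) / 12),
                             10 + 4 * cos(2 * pi * (m - 8) / 12)),
               lat = sst_lat, trend = sst_trend, sigma = sst_sigma),
    zero_p = cbind(diatom = zero_d, dinoflagellate = zero_r)
  )
}

# fast MCMC protocols for tests
fast_config <- function(response = "y", variant = "tst", seed = 1, ...) {
  model_config(response = response, variant = variant, chains = 2,
               iterations = 1000, burnin = 300, thin = 1, seed = seed, ...)
}

quick_config <- function(response = "y", variant = "tst", seed = 1, ...) {
  model_config(response = response, variant = variant, chains = 1,
               iterations = 900, burnin = 200, thin = 1, seed = seed, ...)
}

# small deterministic trait table (no missing sizes)
tiny_traits <- function() {
  data.frame(
    taxon = c("dia_a", "dia_b", "din_a", "din_b"),
    group = c("diatom", "diatom", "dinoflagellate", "dinoflagellate"),
    volume_um3 = c(500, 2000, 5000, 20000),
    stringsAsFactors = FALSE
  )
}
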