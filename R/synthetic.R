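#' Generate a synthetic taxon trait table
#'
#' Draws per-taxon mean cell volumes log-normally, separately for diatoms
#' (median 1e3 um^3 by default) and dinoflagellates (median 1e4 um^3),
#' emulating a trait table of average cell sizes per taxon. Optionally one
#' taxon per group is given a missing volume to exercise the downstream
#' size-imputation rule.
#'
#' @param n_diatoms,n_dinos Number of taxa per group (>= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param median_volume Named vector of median cell volumes (um^3) per group.
#' @param sdlog Log-scale standard deviation of the volume distribution.
#' @param missing_volume If `TRUE` (default), one randomly chosen taxon per
#'   group with at least two taxa has its volume set to `NA`.
#'
#' @return data.frame with columns `taxon`, `group`, `volume_um3`.
#' @export
#' @examples
#' generate_taxon_table(3, 3, seed = 1)
generate_taxon_table <- function(n_diatoms, n_dinos, seed,
                                 median_volume = c(diatom = 1e3, dinoflagellate = 1e4),
                                 sdlog = 1, missing_volume = TRUE) {
  if (n_diatoms < 1 || n_dinos < 1) stop("taxon counts must be >= 1")
  set.seed(seed)
  one_group <- function(n, group, med) {
    v <- stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
    if (missing_volume && n >= 2) v[sample.int(n, 1)] <- NA_real_
    data.frame(
      taxon = sprintf("%s_%02d", substr(group, 1, 4), seq_len(n)),
      group = group, volume_um3 = v, stringsAsFactors = FALSE
    )
  }
  rbind(
    one_group(n_diatoms, "diatom", median_volume[["diatom"]]),
    one_group(n_dinos, "dinoflagellate", median_volume[["dinoflagellate"]])
  )
}

#' Simulate a gridded sea-surface temperature field
#'
#' Generates SST for the full factorial grid of province x latitude band x
#' month x year from the additive decomposition
#' `SST = alpha[m,A] + rho[A] * (l - lbar[A]) + beta[A] * (y - 1960) + eps`,
#' with `eps ~ Normal(0, sigma_sst[A]^2)`. The realized residual is retained
#' in the output column `true_anomaly` as simulator ground truth: it is the
#' quantity the anomaly model attempts to recover, and the quantity the
#' abundance simulator feeds through the anomaly effect.
#'
#' @param params A `generative_params` object.
#' @param years Integer vector of years (non-empty).
#' @param seed Integer seed.
#' @param band_width Latitude band width in degrees.
#'
#' @return data.frame with columns `province`, `latitude` (band center),
#'   `year`, `month`, `sst` (degrees C), `true_anomaly` (degrees C).
#' @export
simulate_sst <- function(params, years = 1960:2017, seed = 1, band_width = 2.5) {
  if (length(years) == 0) stop("years must be non-empty")
  set.seed(seed)
  prov <- params$provinces
  out <- vector("list", nrow(prov))
  for (i in seq_len(nrow(prov))) {
    bands <- province_bands(prov[i, ], band_width)
    if (length(bands) == 0) stop("province ", prov$province[i], " has an empty latitude grid")
    g <- expand.grid(latitude = bands, month = 1:12, year = years,
                     KEEP.OUT.ATTRS = FALSE)
    lbar <- mean(bands)
    eps <- stats::rnorm(nrow(g), 0, params$sst$sigma[i])
    g$province <- prov$province[i]
    g$sst <- params$sst$month[i, g$month] +
      params$sst$lat[i] * (g$latitude - lbar) +
      params$sst$trend[i] * (g$year - 1960) + eps
    g$true_anomaly <- eps
    out[[i]] <- g[, c("province", "latitude", "year", "month", "sst", "true_anomaly")]
  }
  do.call(rbind, out)
}

#' Simulate taxon-resolved abundance records
#'
#' For every cell (province, band, month, year) of the SST grid and each
#' functional group, draws the cell's true log group biomass from the
#' time-space-temperature mean structure (month effect + latitude gradient +
#' interannual trend + anomaly effect applied to the cell's realized SST
#' residual + optional decade step) plus `Normal(0, sigma^2)` noise, then
#' either suppresses the group entirely with the configured zero-inflation
#' probability or partitions the biomass across the group's taxa with
#' symmetric Dirichlet(1) weights and divides by per-cell carbon to obtain
#' abundances. Each group's log biomass is drawn from its own mean structure,
#' so the logit diatom index of a cell follows the same additive form with
#' parameters equal to the diatom-minus-dinoflagellate differences (the
#' default parameter set keeps the configured `logit_index` block equal to
#' those differences).
#'
#' Abundances are real-valued "abundance units" proportional to cell number
#' density; no volume-filtered conversion to cells per litre is attempted.
#' Taxa with missing volume are excluded from the partition (their biomass
#' contribution is handled downstream by size imputation).
#'
#' @param params A `generative_params` object.
#' @param traits Trait table from [generate_taxon_table()].
#' @param sst SST grid from [simulate_sst()] (must contain `true_anomaly`).
#' @param seed Integer seed.
#'
#' @return data.frame with columns `taxon`, `group`, `abundance`, `latitude`,
#'   `longitude`, `year`, `month`, `province`.
#' @export
simulate_abundance <- function(params, traits, sst, seed = 1) {
  if (!all(c("diatom", "dinoflagellate") %in% traits$group)) {
    stop("traits must contain both functional groups")
  }
  if (is.null(sst$true_anomaly)) stop("sst grid must carry the realized residual ('true_anomaly')")
  set.seed(seed)
  prov <- params$provinces
  traits <- impute_missing_size(traits)
  known <- traits[!traits$imputed_size, , drop = FALSE]

  groups <- c(diatom = "log_diatom", dinoflagellate = "log_dino")
  n <- nrow(sst)
  pidx <- match(sst$province, prov$province)
  if (anyNA(pidx)) stop("sst grid contains provinces absent from params")
  lbar <- tapply(sst$latitude, sst$province, mean)[sst$province]

  # total log biomass and diatom share per cell
  mu_of <- function(resp) {
    r <- params$responses[[resp]]
    dec <- pmin(pmax(floor(sst$year / 10) * 10, 1960), 1960 + 10 * (ncol(r$decade) - 1))
    didx <- (dec - 1960) / 10 + 1
    r$month[cbind(pidx, sst$month)] +
      r$lat[pidx] * (sst$latitude - lbar) +
      r$trend[pidx] * (sst$year - 1960) +
      r$anom[pidx] * sst$true_anomaly +
      r$decade[cbind(pidx, didx)]
  }
  log_q <- mu_of("log_diatom") + stats::rnorm(n, 0, params$responses$log_diatom$sigma[pidx])
  log_r <- mu_of("log_dino") + stats::rnorm(n, 0, params$responses$log_dino$sigma[pidx])

  zero_d <- stats::runif(n) < params$zero_p[cbind(pidx, 1)]
  zero_r <- stats::runif(n) < params$zero_p[cbind(pidx, 2)]

  lat_obs <- sst$latitude + stats::runif(n, -1.24, 1.24)
  lon_obs <- stats::runif(n, -40, 0)

  recs <- vector("list", 2L)
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    tx <- known[known$group == gname, , drop = FALSE]
    if (nrow(tx) == 0) stop("no taxa with known size in group ", gname)
    keep <- if (gname == "diatom") !zero_d else !zero_r
    logb <- if (gname == "diatom") log_q else log_r
    idx <- which(keep)
    k <- nrow(tx)
    # symmetric Dirichlet(1) partition per cell
    w <- matrix(stats::rexp(length(idx) * k), ncol = k)
    w <- w / rowSums(w)
    biomass <- exp(logb[idx])  # ug C per cell
    ab <- sweep(w, 1, biomass, "*")
    ab <- sweep(ab, 2, tx$carbon_pg * 1e-6, "/")  # abundance units
    recs[[gi]] <- data.frame(
      taxon = rep(tx$taxon, each = length(idx)),
      group = rep(gname, length(idx) * k),
      abundance = as.vector(ab),
      latitude = rep(lat_obs[idx], k),
      longitude = rep(lon_obs[idx], k),
      year = rep(sst$year[idx], k),
      month = rep(sst$month[idx], k),
      province = rep(sst$province[idx], k),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(recs[[1]], recs[[2]])
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper producing a coherent set of artifacts: trait table,
#' SST grid, abundance records and the generative truth, from one seed.
#'
#' @inheritParams simulate_sst
#' @param n_diatoms,n_dinos Taxa per group.
#' @return list with elements `params`, `traits`, `sst`, `abundance`.
#' @export
simulate_study <- function(params = default_generative_params(),
                           years = 1960:2017, seed = 1,
                           n_diatoms = 20, n_dinos = 20) {
  traits <- generate_taxon_table(n_diatoms, n_dinos, seed = seed + 1L)
  sst <- simulate_sst(params, years = years, seed = seed + 2L)
  ab <- simulate_abundance(params, traits, sst, seed = seed + 3L)
  list(params = params, traits = traits, sst = sst, abundance = ab)
}

#' Simulate bin-level responses directly from the trend model
#'
#' Bypasses the abundance/aggregation stages and draws one response value per
#' (province, band, month, year) cell directly from the hierarchical mean
#' structure plus Normal noise, with the SST anomaly taken as the realized
#' residual of a simulated SST grid. This is the workhorse for parameter
#' recovery studies: the fitted model is exactly the generative model.
#'
#' @param params A `generative_params` object.
#' @param response One of `"log_diatom"`, `"log_dino"`, `"logit_index"`.
#' @param years Integer vector of years.
#' @param seed Integer seed.
#' @param band_width Latitude band width in degrees.
#'
#' @return list with `bins` (data.frame: province, latitude, year, month,
#'   decade, response, plus the response value in column `y`), `anomalies`
#'   (data.frame keyed like the bins with column `anomaly` = the realized SST
#'   residual) and `truth` (the generative parameter block used).
#' @export
simulate_bins <- function(params, response = "logit_index",
                          years = 1960:1999, seed = 1, band_width = 2.5) {
  stopifnot(response %in% names(params$responses))
  sst <- simulate_sst(params, years = years, seed = seed, band_width = band_width)
  set.seed(seed + 1000L)
  r <- params$responses[[response]]
  prov <- params$provinces
  pidx <- match(sst$province, prov$province)
  lbar <- tapply(sst$latitude, sst$province, mean)[sst$province]
  dec <- pmin(pmax(floor(sst$year / 10) * 10, 1960), 1960 + 10 * (ncol(r$decade) - 1))
  didx <- (dec - 1960) / 10 + 1
  mu <- r$month[cbind(pidx, sst$month)] +
    r$lat[pidx] * (sst$latitude - lbar) +
    r$trend[pidx] * (sst$year - 1960) +
    r$anom[pidx] * sst$true_anomaly +
    r$decade[cbind(pidx, didx)]
  y <- mu + stats::rnorm(nrow(sst), 0, r$sigma[pidx])
  bins <- data.frame(
    province = sst$province, latitude = sst$latitude, year = sst$year,
    month = sst$month, decade = decade_label(sst$year), y = y,
    stringsAsFactors = FALSE
  )
  anomalies <- data.frame(
    province = sst$province, latitude = sst$latitude, year = sst$year,
    month = sst$month, anomaly = sst$true_anomaly, stringsAsFactors = FALSE
  )
  list(bins = bins, anomalies = anomalies, truth = r, response = response)
}
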