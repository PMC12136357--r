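# End-to-end pipeline over on-disk CSV/YAML artifacts. Each stage reads the
# artifacts the previous stage wrote and fails with an explicit message
# naming any absent file. A thin command-line wrapper lives at
# inst/scripts/pipeline.R.

require_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop("missing input file '", path, "'; run the ", produced_by,
         " stage first", call. = FALSE)
  }
  path
}

#' Write generative ground truth to YAML
#'
#' @param params A `generative_params` object.
#' @param path Output path.
#' @export
write_truth_yaml <- function(params, path) {
  to_plain <- function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else
      if (is.list(x)) lapply(x, to_plain) else as.vector(x)
  }
  yaml::write_yaml(list(
    provinces = params$provinces$province,
    lat_min = params$provinces$lat_min,
    lat_max = params$provinces$lat_max,
    responses = to_plain(params$responses),
    sst = to_plain(params$sst),
    zero_p = to_plain(params$zero_p)
  ), path)
  invisible(path)
}

#' Simulate stage: write synthetic study artifacts
#'
#' Writes `abundance.csv`, `traits.csv`, `sst.csv` and `truth.yaml` into
#' `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give byte-identical artifacts.
#' @param params Generative parameters.
#' @param years Simulated year range.
#' @return Invisibly, the list of file paths written.
#' @export
pipeline_simulate <- function(dir, seed = 1, params = default_generative_params(),
                              years = 1960:2017) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(params, years = years, seed = seed)
  paths <- file.path(dir, c("abundance.csv", "traits.csv", "sst.csv", "truth.yaml"))
  utils::write.csv(study$abundance, paths[1], row.names = FALSE)
  utils::write.csv(study$traits, paths[2], row.names = FALSE)
  utils::write.csv(study$sst, paths[3], row.names = FALSE)
  write_truth_yaml(params, paths[4])
  invisible(paths)
}

#' Prepare stage: biomass conversion, binning, imputation, anomalies
#'
#' Reads the simulate-stage artifacts and writes `bins.csv` (imputed bins
#' with flags, diatom index and its logit) and `anomalies.csv`.
#'
#' @param dir Artifact directory.
#' @param anomaly_mode `"fast"` or `"bayes"` SST anomaly construction.
#' @param config MCMC configuration for the Bayesian anomaly mode.
#' @return Invisibly, the paths written.
#' @export
pipeline_prepare <- function(dir, anomaly_mode = "fast",
                             config = model_config()) {
  ab <- utils::read.csv(require_file(file.path(dir, "abundance.csv"), "simulate"))
  tr <- utils::read.csv(require_file(file.path(dir, "traits.csv"), "simulate"))
  sst <- utils::read.csv(require_file(file.path(dir, "sst.csv"), "simulate"))
  bins <- prepare_bins(ab, tr)
  anom <- sst_anomaly(sst, config, mode = anomaly_mode)
  paths <- file.path(dir, c("bins.csv", "anomalies.csv"))
  utils::write.csv(bins, paths[1], row.names = FALSE)
  utils::write.csv(anom, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Fit stage: hierarchical trend model
#'
#' Reads `bins.csv` and `anomalies.csv`, fits the configured model and
#' writes the posterior draws (`draws_<response>_<variant>.csv`, columns
#' parameter/chain/draw/value) and effect summaries
#' (`summary_<response>_<variant>.csv`).
#'
#' @param dir Artifact directory.
#' @param config A [model_config()].
#' @return The fitted `plankton_fit`, invisibly.
#' @export
pipeline_fit <- function(dir, config = model_config()) {
  bins <- utils::read.csv(require_file(file.path(dir, "bins.csv"), "prepare"))
  anom <- if (config$variant == "tst") {
    utils::read.csv(require_file(file.path(dir, "anomalies.csv"), "prepare"))
  } else NULL
  fit <- fit_trend_model(bins, anom, config)
  tag <- paste0(config$response, "_", config$variant)
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, draw = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, paste0("draws_", tag, ".csv")),
                   row.names = FALSE)
  utils::write.csv(slope_summary(fit),
                   file.path(dir, paste0("summary_", tag, ".csv")),
                   row.names = FALSE)
  invisible(fit)
}

#' Check stage: posterior predictive diagnostics and Bayesian R-squared
#'
#' @param dir Artifact directory.
#' @param config A [model_config()].
#' @param seed Seed for the predictive replicates.
#' @return Invisibly, the diagnostics data.frame written to
#'   `diagnostics_<response>_<variant>.csv`.
#' @export
pipeline_check <- function(dir, config = model_config(), seed = 1) {
  bins <- utils::read.csv(require_file(file.path(dir, "bins.csv"), "prepare"))
  anom <- if (config$variant == "tst") {
    utils::read.csv(require_file(file.path(dir, "anomalies.csv"), "prepare"))
  } else NULL
  fit <- fit_trend_model(bins, anom, config)
  pm <- posterior_predictive_check(fit, "mean", seed = seed)
  pv <- posterior_predictive_check(fit, "variance", seed = seed + 1)
  out <- data.frame(
    response = config$response, variant = config$variant,
    statistic = c("mean", "variance"),
    observed = c(pm$observed, pv$observed),
    p_value = c(pm$p_value, pv$p_value),
    r2 = as.numeric(bayesian_r2(fit))
  )
  utils::write.csv(out, file.path(dir, paste0("diagnostics_", config$response,
                                              "_", config$variant, ".csv")),
                   row.names = FALSE)
  invisible(out)
}

#' Report stage: trends as percent per year and compounded change
#'
#' @param dir Artifact directory.
#' @param config A [model_config()].
#' @param years Compounding horizon.
#' @return Invisibly, the trend report written to
#'   `trends_<response>_<variant>.csv`.
#' @export
pipeline_report <- function(dir, config = model_config(), years = 60) {
  bins <- utils::read.csv(require_file(file.path(dir, "bins.csv"), "prepare"))
  anom <- if (config$variant == "tst") {
    utils::read.csv(require_file(file.path(dir, "anomalies.csv"), "prepare"))
  } else NULL
  fit <- fit_trend_model(bins, anom, config)
  rep <- trend_report(fit, years = years)
  clim <- monthly_climatology(fit)
  utils::write.csv(rep, file.path(dir, paste0("trends_", config$response, "_",
                                              config$variant, ".csv")),
                   row.names = FALSE)
  utils::write.csv(clim, file.path(dir, paste0("climatology_", config$response,
                                               "_", config$variant, ".csv")),
                   row.names = FALSE)
  invisible(rep)
}
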