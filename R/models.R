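#' MCMC configuration for the hierarchical models
#'
#' Defaults follow the original fitting protocol: three parallel chains of
#' 10,000 iterations, the first 4,000 discarded as burn-in and the remainder
#' thinned by 10, with InvGamma(0.1, 0.1) hyper-variances, Uniform(0, 10)
#' province standard deviations, and the Extended Bayesian LASSO layer
#' lambda ~ Gamma(1, 1), xi_A ~ Uniform(0, 2). The blocked Gibbs sampler used
#' here mixes well, so substantially fewer draws than the default protocol
#' are usually adequate; reduced settings are used throughout the test suite.
#'
#' @param response One of `"log_diatom"`, `"log_dino"`, `"log_total"`,
#'   `"logit_index"`.
#' @param variant `"tst"` (time-space-temperature) or `"ts"` (time-space,
#'   with decadal steps under the LASSO prior).
#' @param chains,iterations,burnin,thin MCMC protocol.
#' @param ig_shape,ig_rate InvGamma hyper-prior on the exchangeable effect
#'   variances.
#' @param sd_bound Upper bound of the uniform prior on province residual
#'   standard deviations.
#' @param lambda_shape,lambda_rate Gamma prior on the global LASSO scale.
#' @param xi_bound Upper bound of the uniform prior on the province LASSO
#'   multipliers.
#' @param rhat_threshold,min_ess Convergence flags: split-chain potential
#'   scale reduction below `rhat_threshold` and effective sample size above
#'   `min_ess` for every parameter.
#' @param seed Integer seed.
#' @return A `model_config` list.
#' @export
model_config <- function(response = "logit_index",
                         variant = c("tst", "ts"),
                         chains = 3, iterations = 10000, burnin = 4000,
                         thin = 10, ig_shape = 0.1, ig_rate = 0.1,
                         sd_bound = 10, lambda_shape = 1, lambda_rate = 1,
                         xi_bound = 2, rhat_threshold = 1.05, min_ess = 100,
                         seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(burnin < iterations, thin >= 1, chains >= 1,
            ig_shape > 0, ig_rate > 0, sd_bound > 0, xi_bound > 0)
  structure(
    list(response = response, variant = variant, chains = chains,
         iterations = iterations, burnin = burnin, thin = thin,
         ig_shape = ig_shape, ig_rate = ig_rate, sd_bound = sd_bound,
         lambda_shape = lambda_shape, lambda_rate = lambda_rate,
         xi_bound = xi_bound, rhat_threshold = rhat_threshold,
         min_ess = min_ess, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Evaluate the hierarchical linear predictor for one bin
#'
#' Time-space-temperature form:
#' `mu = theta[month] + eta (l - lbar) + gamma (year - 1960) + phi * anomaly`;
#' the time-space form replaces the anomaly term with the decade step
#' `delta[decade]`.
#'
#' @param params List with per-province elements: `theta` (12 month effects),
#'   `eta`, `gamma`, `lbar`, and `phi` (tst) or `delta` (named by decade
#'   label, ts).
#' @param bin List or one-row data.frame with `province`, `latitude`,
#'   `month`, `year`.
#' @param anomaly SST anomaly (degrees C); required for the tst variant.
#' @param variant `"tst"` or `"ts"`.
#' @return The linear predictor (log or logit scale).
#' @export
#' @examples
#' pars <- list(A = list(theta = rep(1, 12), eta = 0.1, gamma = 0.01, lbar = 50, phi = 0))
#' linear_predictor(pars, list(province = "A", latitude = 52.5, month = 3, year = 1970),
#'                  anomaly = 0)  # 1.35
linear_predictor <- function(params, bin, anomaly = NULL,
                             variant = c("tst", "ts")) {
  variant <- match.arg(variant)
  pp <- params[[bin$province]]
  if (is.null(pp)) stop("unknown province: ", bin$province)
  mu <- pp$theta[bin$month] + pp$eta * (bin$latitude - pp$lbar) +
    pp$gamma * (bin$year - 1960)
  if (variant == "tst") {
    if (is.null(anomaly)) stop("the time-space-temperature variant requires an anomaly")
    mu <- mu + pp$phi * anomaly
  } else {
    mu <- mu + pp$delta[[as.character(decade_label(bin$year))]]
  }
  unname(mu)
}

response_vector <- function(bins, response) {
  y <- switch(response,
    log_diatom = log(bins$q),
    log_dino = log(bins$r),
    log_total = log(bins$q + bins$r),
    logit_index = bins$h,
    y = bins$y,
    stop("unknown response: ", response)
  )
  if (is.null(y)) stop("bins lack the columns needed for response ", response)
  y
}

#' Fit a hierarchical trend model to binned biomass data
#'
#' Fits the Time-Space-Temperature model (month effects, latitudinal
#' gradient, interannual trend, SST-anomaly effect; all province-specific
#' with exchangeable hierarchical priors) or the Time-Space model (anomaly
#' replaced by decadal steps under the Extended Bayesian LASSO prior) by
#' blocked Gibbs sampling.
#'
#' @param bins Imputed bins (see [impute_zeros()]), or any data.frame with
#'   `province`, `latitude`, `year`, `month` and the response columns. A
#'   column `y` is used directly when `config$response == "y"`.
#' @param anomalies For the tst variant: data.frame with `province`,
#'   `latitude`, `year`, `month`, `anomaly`, keyed like the bins.
#' @param config A [model_config()].
#' @param terms Optional override of the design terms (used by
#'   [variable_importance()] to omit predictors).
#' @return Object of class `plankton_fit` carrying the posterior draws
#'   (a `coda::mcmc.list`), the design, and a convergence summary. A fit
#'   whose chains fail the convergence thresholds is returned with
#'   `converged = FALSE` and a warning, never silently.
#' @export
fit_trend_model <- function(bins, anomalies = NULL, config = model_config(),
                            terms = NULL) {
  if (length(unique(bins$year)) < 2) stop("need at least 2 years of data")
  y <- response_vector(bins, config$response)
  df <- bins
  if (is.null(terms)) {
    terms <- if (config$variant == "tst") {
      c("month", "lat", "trend", "anom")
    } else {
      c("month", "lat", "trend", "decade")
    }
  }
  if ("anom" %in% terms) {
    if (is.null(anomalies)) stop("the time-space-temperature variant requires anomalies")
    df$anomaly <- match_anomalies(bins, anomalies)
  }
  design <- build_design(df, y, terms = terms)
  draws <- run_gibbs(design, config)
  conv <- convergence_summary(draws, config$rhat_threshold, config$min_ess)
  if (!conv$converged) {
    warning("MCMC convergence thresholds not met; inspect $convergence")
  }
  structure(
    list(draws = draws, design = design, config = config,
         convergence = conv$table, converged = conv$converged,
         response = config$response, variant = config$variant),
    class = "plankton_fit"
  )
}

# join anomalies onto bins by (province, latitude, year, month)
match_anomalies <- function(bins, anomalies) {
  kb <- paste(bins$province, bins$latitude, bins$year, bins$month)
  ka <- paste(anomalies$province, anomalies$latitude, anomalies$year,
              anomalies$month)
  idx <- match(kb, ka)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " bins have no matching SST anomaly")
  }
  anomalies$anomaly[idx]
}

#' @export
print.plankton_fit <- function(x, ...) {
  cat("Hierarchical trend model fit\n")
  cat("  response: ", x$response, "  variant: ", x$variant, "\n", sep = "")
  cat("  provinces:", paste(x$design$provinces, collapse = ", "), "\n")
  cat("  draws:", coda::niter(x$draws) * coda::nchain(x$draws),
      "retained over", coda::nchain(x$draws), "chains\n")
  cat("  converged:", x$converged,
      sprintf("(max split-Rhat %.3f)", max(x$convergence$rhat)), "\n")
  invisible(x)
}

# combined draws matrix across chains
draws_matrix <- function(fit) {
  do.call(rbind, lapply(fit$draws, as.matrix))
}

# fitted-value draws: n_bins x n_draws matrix in the original bin order
fitted_draws <- function(fit) {
  dm <- draws_matrix(fit)
  n <- fit$design$n_total
  out <- matrix(NA_real_, n, nrow(dm))
  for (A in fit$design$provinces) {
    pd <- fit$design$prov_data[[A]]
    B <- dm[, match(province_param_names(fit$design, A), colnames(dm)), drop = FALSE]
    out[pd$rows, ] <- pd$X %*% t(B)
  }
  out
}

# ordered coefficient names for one province, matching design columns
province_param_names <- function(design, A) {
  cls <- design$col_class
  sym <- design$symbols
  out <- character(length(cls))
  month_count <- 0L
  dec_i <- 0L
  for (j in seq_along(cls)) {
    out[j] <- switch(cls[j],
      month = { month_count <- month_count + 1L
                sprintf("%s[%s,%d]", sym[["month"]], A, month_count) },
      decade = { dec_i <- dec_i + 1L
                 sprintf("%s[%s,%d]", sym[["decade"]], A, design$decades[dec_i]) },
      sprintf("%s[%s]", sym[[cls[j]]], A)
    )
  }
  out
}

# residual sd draws per province: n_draws x n_prov
sigma_draws <- function(fit) {
  dm <- draws_matrix(fit)
  dm[, paste0("sigma[", fit$design$provinces, "]"), drop = FALSE]
}

#' Posterior summaries of the model effects
#'
#' Medians with 66% and 95% credible intervals (sample quantiles at 2.5, 17,
#' 50, 83 and 97.5 percent) for the interannual trends and, where present,
#' the anomaly effects, latitudinal gradients and month effects.
#'
#' @param fit A `plankton_fit`.
#' @param parameters Character vector of parameter symbols to summarize
#'   (default all coefficient classes in the model).
#' @return data.frame with columns `province`, `parameter`, `month`/`decade`
#'   index where applicable, and the five quantiles `q2.5`, `q17`, `q50`,
#'   `q83`, `q97.5`.
#' @export
slope_summary <- function(fit, parameters = NULL) {
  dm <- draws_matrix(fit)
  design <- fit$design
  sym <- design$symbols
  if (is.null(parameters)) {
    parameters <- unname(sym[unique(design$col_class)])
  }
  rows <- list()
  for (A in design$provinces) {
    nm <- province_param_names(design, A)
    cl <- design$col_class
    for (j in seq_along(nm)) {
      psym <- sym[[cl[j]]]
      if (!psym %in% parameters) next
      qs <- stats::quantile(dm[, nm[j]], c(0.025, 0.17, 0.5, 0.83, 0.975),
                            names = FALSE)
      idx <- if (cl[j] == "month") {
        as.integer(sub(".*,(\\d+)\\]", "\\1", nm[j]))
      } else if (cl[j] == "decade") {
        as.integer(sub(".*,(\\d+)\\]", "\\1", nm[j]))
      } else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        province = A, parameter = psym, index = idx,
        q2.5 = qs[1], q17 = qs[2], q50 = qs[3], q83 = qs[4], q97.5 = qs[5],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
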