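#' Fit the Bayesian SST decomposition
#'
#' Decomposes gridded sea-surface temperature into province-specific month
#' effects, a latitudinal gradient and a linear interannual trend,
#' `SST = alpha[m,A] + rho_A (l - lbar_A) + beta_A (y - 1960) + sst`, with
#' `sst ~ Normal(0, sigma_SST,A^2)` the temperature anomaly. Priors are
#' exchangeable Normals on `alpha`, `rho`, `beta` with InvGamma(0.1, 0.1)
#' hyper-variances and Uniform(0, 10) on `sigma_SST,A`.
#'
#' A deterministic `"fast"` mode computes ordinary least-squares residuals of
#' the same decomposition (one linear model per province); at these data
#' sizes and with these diffuse priors the two modes agree closely. The
#' Bayesian mode is the default.
#'
#' @param records data.frame with `province`, `latitude`, `year`, `month`,
#'   `sst` (degrees C).
#' @param config A [model_config()]; only the MCMC protocol fields are used.
#' @param mode `"bayes"` or `"fast"`.
#' @return Object of class `sst_fit`.
#' @export
fit_sst_model <- function(records, config = model_config(), mode = c("bayes", "fast")) {
  mode <- match.arg(mode)
  for (A in unique(records$province)) {
    d <- records[records$province == A, ]
    if (length(unique(d$year)) < 2 || length(unique(d$latitude)) < 2) {
      stop("degenerate SST design in province ", A,
           ": need at least 2 years and 2 latitude bands")
    }
  }
  symbols <- c(month = "alpha", lat = "rho", trend = "beta")
  if (mode == "fast") {
    res <- numeric(nrow(records))
    coefs <- list()
    for (A in unique(records$province)) {
      sel <- records$province == A
      d <- records[sel, ]
      lbar <- mean(d$latitude)
      fit <- stats::lm(sst ~ 0 + factor(month, levels = 1:12) +
                         I(latitude - lbar) + I(year - 1960), data = d)
      res[sel] <- stats::residuals(fit)
      coefs[[A]] <- stats::coef(fit)
    }
    return(structure(
      list(mode = "fast", records = records, residuals = res, coef = coefs),
      class = "sst_fit"
    ))
  }
  design <- build_design(records, records$sst,
                         terms = c("month", "lat", "trend"), symbols = symbols)
  draws <- run_gibbs(design, config)
  conv <- convergence_summary(draws, config$rhat_threshold, config$min_ess)
  if (!conv$converged) {
    warning("SST model: MCMC convergence thresholds not met")
  }
  structure(
    list(mode = "bayes", records = records, draws = draws, design = design,
         config = config, convergence = conv$table, converged = conv$converged),
    class = "sst_fit"
  )
}

#' @export
print.sst_fit <- function(x, ...) {
  cat("SST decomposition (", x$mode, " mode), ",
      nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Per-record SST anomalies
#'
#' For the Bayesian fit the anomaly of a record is the posterior median of
#' its residual term; for the fast fit it is the least-squares residual.
#'
#' @param fit An `sst_fit`.
#' @return data.frame keyed like the input records (`province`, `latitude`,
#'   `year`, `month`) with column `anomaly` (degrees C).
#' @export
compute_anomaly <- function(fit) {
  recs <- fit$records
  out <- recs[, c("province", "latitude", "year", "month")]
  if (fit$mode == "fast") {
    out$anomaly <- fit$residuals
    return(out)
  }
  dm <- draws_matrix(fit)
  anom <- numeric(nrow(recs))
  for (A in fit$design$provinces) {
    pd <- fit$design$prov_data[[A]]
    B <- dm[, match(province_param_names(fit$design, A), colnames(dm)),
            drop = FALSE]
    res <- pd$y - pd$X %*% t(B)     # n_A x n_draws residual draws
    anom[pd$rows] <- apply(res, 1, stats::median)
  }
  out$anomaly <- anom
  out
}

#' One-call SST anomaly construction
#'
#' @inheritParams fit_sst_model
#' @return data.frame of anomalies, see [compute_anomaly()].
#' @export
sst_anomaly <- function(records, config = model_config(), mode = c("bayes", "fast")) {
  compute_anomaly(fit_sst_model(records, config, mode))
}
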