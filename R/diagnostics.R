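#' Posterior predictive check with a Bayesian p-value
#'
#' Draws `n_rep` replicate datasets from the fitted model (each replicate
#' uses one retained posterior draw and simulates
#' `y_rep ~ Normal(mu, sigma_A^2)` at the observed design points), computes
#' the test statistic on each, and reports the Bayesian p-value
#' `P(T_rep >= T_obs)`. Statistics may be computed pooled over all bins
#' (default) or within each province.
#'
#' @param fit A `plankton_fit`.
#' @param statistic `"mean"` or `"variance"`.
#' @param n_rep Number of replicates (>= 10; default 100).
#' @param seed Integer seed for the replicate simulation.
#' @param scope `"pooled"` or `"province"`.
#' @param observed Optional replacement observed response vector (aligned
#'   with the bins the model was fit to); defaults to the fitted data.
#' @return Object of class `ppc_summary`: statistic name, observed value(s),
#'   replicate values, p-value(s). Values near 0 or 1 flag misfit; the
#'   conventional comfortable band is 0.25--0.75.
#' @export
posterior_predictive_check <- function(fit, statistic = c("mean", "variance"),
                                       n_rep = 100, seed = 1,
                                       scope = c("pooled", "province"),
                                       observed = NULL) {
  statistic <- match.arg(statistic)
  scope <- match.arg(scope)
  if (n_rep < 10) stop("n_rep must be at least 10 for a stable p-value")
  stat_fun <- if (statistic == "mean") mean else stats::var
  set.seed(seed)
  mu <- fitted_draws(fit)                 # n_bins x n_draws
  sig <- sigma_draws(fit)                 # n_draws x n_prov
  ndraws <- ncol(mu)
  use <- round(seq(1, ndraws, length.out = n_rep))
  prov_of <- character(fit$design$n_total)
  y_obs <- numeric(fit$design$n_total)
  for (A in fit$design$provinces) {
    pd <- fit$design$prov_data[[A]]
    prov_of[pd$rows] <- A
    y_obs[pd$rows] <- pd$y
  }
  if (!is.null(observed)) {
    stopifnot(length(observed) == length(y_obs))
    y_obs <- observed
  }
  prov_col <- match(prov_of, fit$design$provinces)
  groups <- c(list(pooled = seq_along(y_obs)),
              split(seq_along(y_obs), prov_of))
  rep_stats <- matrix(NA_real_, length(use), length(groups),
                      dimnames = list(NULL, names(groups)))
  for (i in seq_along(use)) {
    k <- use[i]
    y_rep <- stats::rnorm(length(y_obs), mu[, k], sig[k, prov_col])
    rep_stats[i, ] <- vapply(groups, function(g) stat_fun(y_rep[g]), numeric(1))
  }
  obs_stats <- vapply(groups, function(g) stat_fun(y_obs[g]), numeric(1))
  pvals <- vapply(seq_along(groups), function(j) {
    mean(rep_stats[, j] >= obs_stats[j])
  }, numeric(1))
  names(pvals) <- names(groups)
  keep <- if (scope == "pooled") "pooled" else setdiff(names(groups), "pooled")
  structure(
    list(statistic = statistic, scope = scope,
         observed = obs_stats[keep], replicates = rep_stats[, keep, drop = FALSE],
         p_value = pvals[keep], n_rep = n_rep),
    class = "ppc_summary"
  )
}

#' @export
print.ppc_summary <- function(x, ...) {
  cat("Posterior predictive check (", x$statistic, ", ", x$scope, ")\n", sep = "")
  for (nm in names(x$p_value)) {
    flag <- if (x$p_value[nm] < 0.25 || x$p_value[nm] > 0.75) "  <-- outside 0.25-0.75" else ""
    cat(sprintf("  %-8s observed %.4f  p = %.2f%s\n",
                nm, x$observed[nm], x$p_value[nm], flag))
  }
  invisible(x)
}

#' Plot a posterior predictive check
#'
#' Histogram of the replicate statistics with the observed value marked.
#'
#' @param x A `ppc_summary`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.ppc_summary <- function(x, ...) {
  for (nm in names(x$p_value)) {
    graphics::hist(x$replicates[, nm],
                   main = sprintf("%s (%s): p = %.2f", x$statistic, nm, x$p_value[nm]),
                   xlab = paste("replicate", x$statistic), ...)
    graphics::abline(v = x$observed[nm], lwd = 2)
  }
  invisible(x)
}

#' Bayesian R-squared
#'
#' Draws-based definition: for each retained posterior draw,
#' `R2 = var(mu) / (var(mu) + mean(sigma_A(i)^2))`, where `var(mu)` is the
#' variance of the fitted values over bins and the residual variance is the
#' mean of the squared province residual sd over bins. The posterior median
#' over draws is returned, with the full vector of draws as attribute
#' `"draws"`.
#'
#' @param fit A `plankton_fit`.
#' @return Posterior median R-squared in `[0, 1]`.
#' @export
bayesian_r2 <- function(fit) {
  n <- fit$design$n_total
  if (n < 2) stop("Bayesian R2 needs at least 2 bins")
  mu <- fitted_draws(fit)
  sig <- sigma_draws(fit)
  var_mu <- (colSums(mu^2) - n * colMeans(mu)^2) / (n - 1)
  # residual variance pooled over bins = weight by province bin counts
  wts <- vapply(fit$design$prov_data, function(pd) pd$n, numeric(1)) / n
  s2_mean <- as.vector(sig^2 %*% wts)
  r2 <- var_mu / (var_mu + s2_mean)
  structure(stats::median(r2), draws = r2)
}

#' Leave-one-predictor-out variable importance
#'
#' Refits the model omitting one predictor at a time and reports the drop in
#' Bayesian R-squared relative to the full model. Omitting the month effects
#' replaces them with a single province intercept (so province-level means
#' remain identified); omitting latitude or the anomaly simply drops the
#' term.
#'
#' @param bins Imputed bins.
#' @param anomalies Anomaly table (for tst fits).
#' @param config A [model_config()].
#' @param predictors Predictors to omit, subset of
#'   `c("month", "latitude", "anomaly")`.
#' @return data.frame with `predictor`, `r2_full`, `r2_without`, `delta_r2`.
#' @export
variable_importance <- function(bins, anomalies = NULL,
                                config = model_config(),
                                predictors = c("month", "latitude", "anomaly")) {
  full_terms <- if (config$variant == "tst") {
    c("month", "lat", "trend", "anom")
  } else {
    c("month", "lat", "trend", "decade")
  }
  fit_full <- fit_trend_model(bins, anomalies, config)
  r2_full <- as.numeric(bayesian_r2(fit_full))
  rows <- lapply(predictors, function(p) {
    terms <- switch(p,
      month = c("intercept", setdiff(full_terms, "month")),
      latitude = setdiff(full_terms, "lat"),
      anomaly = setdiff(full_terms, "anom"),
      stop("unknown predictor: ", p)
    )
    f <- fit_trend_model(bins, anomalies, config, terms = terms)
    r2 <- as.numeric(bayesian_r2(f))
    data.frame(predictor = p, r2_full = r2_full, r2_without = r2,
               delta_r2 = r2_full - r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
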