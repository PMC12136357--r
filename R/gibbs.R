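# Blocked Gibbs sampler for the hierarchical normal models.
#
# All models in the package share one structure: within province A,
#   y_i ~ Normal(x_i' b_A, sigma_A^2)
# where the columns of the design fall into effect classes (month indicators,
# latitude deviation, year trend, anomaly, decade indicators). Classes other
# than "decade" get exchangeable Normal(0, tau2_class) priors shared across
# provinces with InvGamma(0.1, 0.1) hyper-variances; sigma_A has a
# Uniform(0, 10) prior; the "decade" class gets the Extended Bayesian LASSO
# prior: delta_{d,A} ~ N(0, s2_A), s2_A ~ Exp(rate = lambda_A^2 / 2),
# lambda_A = lambda * xi_A, lambda ~ Gamma(1, 1), xi_A ~ Uniform(0, 2).
# Note Exp is parameterized by rate, so E[s2_A] = 2 / lambda_A^2.
#
# Conditionals: coefficient blocks and hyper-variances are conjugate;
# sigma_A^2 is truncated inverse gamma (flat prior on sigma, not sigma^2);
# the LASSO scales (s2_A, lambda, xi_A) are updated by univariate slice
# sampling. Sufficient statistics (X'X, X'y, y'y) are precomputed once, so
# per-iteration cost is independent of the number of observations.

#' Build per-province design matrices for the hierarchical models
#'
#' @param df data.frame with columns `province`, `latitude`, `year`, `month`,
#'   optionally `anomaly`, and the response.
#' @param y Numeric response vector aligned with `df`.
#' @param terms Character subset of
#'   `c("month", "intercept", "lat", "trend", "anom", "decade")`.
#' @param lbar Optional named vector of centering latitudes per province;
#'   default is the observed mean latitude per province.
#' @param symbols Named map from effect class to parameter symbol used in
#'   draw names.
#' @return A design list consumed by the internal sampler.
#' @keywords internal
build_design <- function(df, y,
                         terms = c("month", "lat", "trend"),
                         lbar = NULL,
                         symbols = c(month = "theta", intercept = "theta0",
                                     lat = "eta", trend = "gamma",
                                     anom = "phi", decade = "delta"),
                         provinces = NULL, decades = NULL) {
  stopifnot(length(y) == nrow(df))
  if (any(!is.finite(y))) stop("response contains non-finite values")
  if (is.null(provinces)) provinces <- sort(unique(df$province))
  if (is.null(lbar)) {
    lbar <- tapply(df$latitude, df$province, mean)[provinces]
  }
  if (is.null(decades)) {
    decades <- if ("decade" %in% terms && nrow(df) > 0) {
      sort(unique(decade_label(df$year)))
    } else integer(0)
  }
  col_class <- character(0)
  col_label <- character(0)
  add <- function(class, labels) {
    col_class <<- c(col_class, rep(class, length(labels)))
    col_label <<- c(col_label, labels)
  }
  if ("month" %in% terms) add("month", sprintf(",%d]", 1:12))
  if ("intercept" %in% terms) add("intercept", "]")
  if ("lat" %in% terms) add("lat", "]")
  if ("trend" %in% terms) add("trend", "]")
  if ("anom" %in% terms) add("anom", "]")
  if ("decade" %in% terms) add("decade", sprintf(",%d]", decades))
  p <- length(col_class)

  prov_data <- lapply(provinces, function(A) {
    rows <- which(df$province == A)
    d <- df[rows, , drop = FALSE]
    X <- matrix(0, length(rows), p)
    j <- 0L
    if ("month" %in% terms) {
      X[cbind(seq_along(rows), d$month)] <- 1
      j <- j + 12L
    }
    if ("intercept" %in% terms) { j <- j + 1L; X[, j] <- 1 }
    if ("lat" %in% terms) { j <- j + 1L; X[, j] <- d$latitude - lbar[[A]] }
    if ("trend" %in% terms) { j <- j + 1L; X[, j] <- d$year - 1960 }
    if ("anom" %in% terms) {
      j <- j + 1L
      if (is.null(d$anomaly)) stop("design requires an 'anomaly' column")
      X[, j] <- d$anomaly
    }
    if ("decade" %in% terms) {
      dd <- match(decade_label(d$year), decades)
      X[cbind(seq_along(rows), j + dd)] <- 1
    }
    list(X = X, y = y[rows], n = length(rows), rows = rows,
         XtX = crossprod(X), Xty = crossprod(X, y[rows])[, 1],
         yty = sum(y[rows]^2))
  })
  names(prov_data) <- provinces
  param_names <- unlist(lapply(provinces, function(A) {
    paste0(symbols[col_class], "[", A, col_label)
  }))
  list(prov_data = prov_data, provinces = provinces, lbar = lbar,
       decades = decades, col_class = col_class, p = p, terms = terms,
       symbols = symbols, param_names = param_names, n_total = length(y))
}

# univariate slice sampler with stepping out and shrinkage (Neal 2003)
slice_sample1 <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > z) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > z) { R <- R + w; k <- k - 1L }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# truncated inverse-gamma draw for sigma^2 under a flat prior on sigma in
# (0, bound): sigma^2 | SS, n ~ InvGamma((n - 1) / 2, SS / 2) 1(sigma < bound)
draw_sigma2 <- function(n, SS, bound = 10) {
  if (n == 0) return(stats::runif(1, 0, bound)^2)
  SS <- max(SS, 1e-12)
  shape <- (n - 1) / 2
  rate <- SS / 2
  lo <- 1 / bound^2   # precision lower bound
  plo <- stats::pgamma(lo, shape, rate = rate)
  if (plo > 1 - 1e-12) return(bound^2 * (1 - 1e-10))
  u <- stats::runif(1, plo, 1)
  1 / stats::qgamma(u, shape, rate = rate)
}

run_gibbs <- function(design, config) {
  provinces <- design$provinces
  nprov <- length(provinces)
  cls <- design$col_class
  p <- design$p
  normal_classes <- setdiff(unique(cls), "decade")
  has_lasso <- "decade" %in% cls
  ndec <- sum(cls == "decade")
  ig_a <- config$ig_shape
  ig_b <- config$ig_rate
  sd_bound <- config$sd_bound

  n_keep <- floor((config$iterations - config$burnin) / config$thin)
  sym <- design$symbols
  extra_names <- c(
    paste0("sigma[", provinces, "]"),
    paste0("sd_", sym[normal_classes]),
    if (has_lasso) c(paste0("sigma_delta[", provinces, "]"),
                     "lambda", paste0("xi[", provinces, "]"))
  )
  all_names <- c(design$param_names, extra_names)

  one_chain <- function(chain) {
    set.seed(config$seed + 1000L * chain)
    # initial values: ridge least squares on the non-decade columns plus
    # chain-specific jitter; decade steps start at zero so the chain starts
    # in the shrinkage basin of the month-vs-decade level ridge (the model
    # has no global intercept, so a constant can trade between theta and
    # delta; the LASSO prior resolves it in favour of small delta)
    nd <- which(cls != "decade")
    b <- lapply(design$prov_data, function(pd) {
      bb <- rep(0, p)
      if (pd$n > length(nd)) {
        bb[nd] <- tryCatch(
          solve(pd$XtX[nd, nd, drop = FALSE] + diag(1e-2, length(nd)),
                pd$Xty[nd]),
          error = function(e) rep(0, length(nd))
        )
      }
      jit <- ifelse(cls == "decade", 0.01, 0.05) * chain
      bb + stats::rnorm(p, 0, jit)
    })
    sigma2 <- vapply(seq_len(nprov), function(i) {
      pd <- design$prov_data[[i]]
      if (pd$n > p + 1) {
        SS <- pd$yty - 2 * sum(b[[i]] * pd$Xty) +
          drop(crossprod(b[[i]], pd$XtX %*% b[[i]]))
        max(SS / max(pd$n - p, 1), 1e-4)
      } else 1
    }, numeric(1))
    # hyper-variances start at the scale of the initial coefficients; the
    # LASSO scale starts small so the level stays in the month effects (see
    # note above) unless the data demand decade steps
    tau2 <- vapply(normal_classes, function(cl) {
      mean(unlist(lapply(b, function(bb) bb[cls == cl]))^2) + 0.1 * chain
    }, numeric(1))
    s2d <- rep(1e-3, nprov)
    lambda <- 1
    xi <- rep(1, nprov)

    out <- matrix(NA_real_, n_keep, length(all_names))
    kept <- 0L
    for (it in seq_len(config$iterations)) {
      prior_prec <- numeric(p)
      for (cl in normal_classes) prior_prec[cls == cl] <- 1 / tau2[[cl]]
      for (i in seq_len(nprov)) {
        pd <- design$prov_data[[i]]
        pp <- prior_prec
        if (has_lasso) pp[cls == "decade"] <- 1 / s2d[i]
        Q <- pd$XtX / sigma2[i]
        diag(Q) <- diag(Q) + pp
        R <- chol(Q)
        m <- backsolve(R, backsolve(R, pd$Xty / sigma2[i], transpose = TRUE))
        b[[i]] <- drop(m + backsolve(R, stats::rnorm(p)))
        SS <- pd$yty - 2 * sum(b[[i]] * pd$Xty) +
          drop(crossprod(b[[i]], pd$XtX %*% b[[i]]))
        sigma2[i] <- draw_sigma2(pd$n, SS, sd_bound)
      }
      for (cl in normal_classes) {
        coefs <- unlist(lapply(b, function(bb) bb[cls == cl]))
        tau2[[cl]] <- 1 / stats::rgamma(1, ig_a + length(coefs) / 2,
                                        rate = ig_b + sum(coefs^2) / 2)
      }
      if (has_lasso) {
        for (i in seq_len(nprov)) {
          ssd <- sum(b[[i]][cls == "decade"]^2)
          lam2 <- (lambda * xi[i])^2
          logf <- function(v) {
            -(ndec / 2) * v - ssd / (2 * exp(v)) - (lam2 / 2) * exp(v) + v
          }
          s2d[i] <- exp(slice_sample1(log(s2d[i]), logf, w = 1))
        }
        cc <- sum(xi^2 * s2d)
        logf_l <- function(w) {
          (2 * nprov + 1) * w - exp(w) - (cc / 2) * exp(2 * w)
        }
        lambda <- exp(slice_sample1(log(lambda), logf_l, w = 1))
        for (i in seq_len(nprov)) {
          logf_x <- function(x) 2 * log(x) - (lambda^2 * s2d[i] / 2) * x^2
          xi[i] <- slice_sample1(xi[i], logf_x, w = 0.5,
                                 lower = 1e-10, upper = config$xi_bound)
        }
      }
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
        kept <- kept + 1L
        out[kept, ] <- c(
          unlist(b), sqrt(sigma2), sqrt(unlist(tau2)),
          if (has_lasso) c(sqrt(s2d), lambda, xi)
        )
      }
    }
    colnames(out) <- all_names
    coda::mcmc(out, start = config$burnin + config$thin, thin = config$thin)
  }

  draws <- coda::mcmc.list(lapply(seq_len(config$chains), one_chain))
  draws
}

# split-chain potential scale reduction factor
split_rhat <- function(draws_list) {
  halves <- list()
  for (ch in draws_list) {
    m <- as.matrix(ch)
    n2 <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(n2), , drop = FALSE],
                             m[(nrow(m) - n2 + 1):nrow(m), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (!is.finite(W) || W <= 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

# convergence summary: split-Rhat and effective sample size per parameter
convergence_summary <- function(draws, rhat_threshold = 1.05, min_ess = 100) {
  m <- as.matrix(draws[[1]])
  rhat <- split_rhat(draws)
  ess <- tryCatch(coda::effectiveSize(draws),
                  error = function(e) rep(NA_real_, ncol(m)))
  tab <- data.frame(parameter = colnames(m), rhat = rhat,
                    ess = as.numeric(ess), stringsAsFactors = FALSE)
  ok <- all(tab$rhat < rhat_threshold, na.rm = TRUE) &&
    all(tab$ess > min_ess, na.rm = TRUE)
  list(table = tab, converged = ok)
}
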