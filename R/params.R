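#' Generative parameters for the synthetic-data simulator
#'
#' Bundles the ground-truth parameters of the generative model used by
#' [simulate_sst()] and [simulate_abundance()], mirroring the structure of
#' the statistical models the package fits: for each response (log diatom
#' biomass, log dinoflagellate biomass, logit diatom index) a set of
#' province-specific month effects, latitudinal gradient, interannual trend,
#' temperature-anomaly effect and residual standard deviation; an SST
#' decomposition (month effects, latitudinal gradient, warming trend,
#' residual sd); zero-inflation probabilities per functional group and
#' province; and optional decadal step effects (default all zero).
#'
#' @param provinces data.frame as returned by [default_provinces()].
#' @param responses Named list with elements `log_diatom`, `log_dino`,
#'   `logit_index`, each a list with `month` (provinces x 12 matrix, log or
#'   logit scale), `lat` (per degree latitude), `trend` (per year), `anom`
#'   (per degree C), `sigma` (> 0), and optionally `decade`
#'   (provinces x decades matrix, default 0).
#' @param sst List with `month` (provinces x 12 matrix, degrees C), `lat`
#'   (degrees C per degree latitude), `trend` (degrees C per year), `sigma`
#'   (degrees C, > 0).
#' @param zero_p Matrix (provinces x 2, columns `diatom`, `dinoflagellate`)
#'   of zero-inflation probabilities in `[0, 1]`.
#'
#' @return An object of class `generative_params`.
#' @seealso [default_generative_params()]
#' @export
generative_params <- function(provinces, responses, sst, zero_p) {
  np <- nrow(provinces)
  for (nm in c("log_diatom", "log_dino", "logit_index")) {
    r <- responses[[nm]]
    if (is.null(r)) stop("responses must contain '", nm, "'")
    if (!is.matrix(r$month) || !all(dim(r$month) == c(np, 12))) {
      stop("responses$", nm, "$month must be a ", np, " x 12 matrix")
    }
    for (f in c("lat", "trend", "anom")) {
      if (length(r[[f]]) != np) stop("responses$", nm, "$", f, " must have length ", np)
    }
    if (any(r$sigma < 0)) stop("residual standard deviations must be >= 0")
    if (is.null(r$decade)) responses[[nm]]$decade <- matrix(0, np, 6)
  }
  if (!all(dim(sst$month) == c(np, 12))) stop("sst$month must be ", np, " x 12")
  if (any(sst$sigma < 0)) stop("sst$sigma must be >= 0")
  if (any(zero_p < 0 | zero_p > 1)) stop("zero-inflation probabilities must lie in [0, 1]")
  structure(
    list(provinces = provinces, responses = responses, sst = sst, zero_p = zero_p),
    class = "generative_params"
  )
}

#' Default generative parameters
#'
#' Ground truth emulating the broad features of North Atlantic CPR data:
#' seasonal cycles with a spring diatom bloom (April--June peak) preceding a
#' July dinoflagellate climax, a diatom index peaking in early spring with an
#' August minimum, weak latitudinal gradients (about 1--2% of variance),
#' province-specific interannual trends of order +/- 0.01--0.02 per year,
#' negative anomaly effects on the diatom index (warm anomalies favour
#' dinoflagellates; near zero in NWCS) and positive effects on both
#' biomasses, and zero-inflation probabilities giving about 5% diatom-zero
#' and 24% dinoflagellate-zero bins among observed bins, with the
#' dinoflagellate zeros concentrated in the two northern provinces.
#'
#' Log-biomass month effects are on the natural-log microgram-carbon scale of
#' aggregated bins; SST month effects are in degrees C.
#'
#' @return A `generative_params` object.
#' @export
#' @examples
#' p <- default_generative_params()
#' p$responses$logit_index$trend
default_generative_params <- function() {
  prov <- default_provinces()
  np <- nrow(prov)
  m <- 1:12
  # seasonal shapes: diatoms peak in May (month 5), dinos in July (month 7),
  # index peaks in April with an August minimum
  shape <- function(peak, amp) amp * cos(2 * pi * (m - peak) / 12)
  month_mat <- function(base, peak, amp) {
    t(vapply(seq_len(np), function(i) base[i] + shape(peak, amp), numeric(12)))
  }
  base_diatom <- c(ARCT = 8.0, SARC = 8.3, NADR = 8.5, NWCS = 8.4, NECS = 8.8)
  base_dino   <- c(ARCT = 7.4, SARC = 8.5, NADR = 8.9, NWCS = 9.2, NECS = 9.2)

  # diatom trends and the index trends follow the reported province pattern;
  # the dinoflagellate trend is their difference so that the logit index of a
  # simulated cell obeys exactly the configured index parameters
  trend_q <- c(-0.008, -0.007, 0.000, 0.018, 0.022)
  trend_h <- c(-0.009, 0.010, 0.007, 0.015, 0.025)
  lat_q   <- c(-0.03, 0.05, 0.05, -0.06, 0.04)
  lat_r   <- c(0.03, -0.02, -0.01, 0.01, -0.02)
  anom_q  <- c(0.30, 0.30, 0.30, 0.35, 0.30)
  anom_r  <- c(0.40, 0.42, 0.40, 0.36, 0.40)
  sigma_g <- rep(0.75, np)

  log_diatom <- list(
    month = month_mat(base_diatom, peak = 5, amp = 1.0),
    lat = lat_q, trend = trend_q, anom = anom_q, sigma = sigma_g
  )
  log_dino <- list(
    month = month_mat(base_dino, peak = 7, amp = 1.0),
    lat = lat_r, trend = trend_q - trend_h, anom = anom_r, sigma = sigma_g
  )
  # NWCS dinoflagellates show the weakest seasonality of the five provinces
  log_dino$month[4, ] <- base_dino[4] + shape(7, 0.35)

  logit_index <- list(
    month = log_diatom$month - log_dino$month,
    lat = lat_q - lat_r, trend = trend_h, anom = anom_q - anom_r,
    sigma = sqrt(2) * sigma_g
  )
  responses <- list(log_diatom = log_diatom, log_dino = log_dino,
                    logit_index = logit_index)

  sst <- list(
    month = month_mat(c(1.5, 5.5, 11.0, 10.5, 11.0), peak = 8, amp = 3.5),
    lat   = rep(-0.30, np),
    trend = c(0.010, 0.015, 0.015, 0.015, 0.020),
    sigma = rep(1.0, np)
  )

  zero_p <- cbind(
    diatom = rep(0.066, np),
    dinoflagellate = c(0.29, 0.28, 0.23, 0.23, 0.23)
  )
  rownames(zero_p) <- prov$province

  generative_params(prov, responses, sst, zero_p)
}

#' @export
print.generative_params <- function(x, ...) {
  cat("Generative parameters for", nrow(x$provinces), "provinces\n")
  cat("  responses: ", paste(names(x$responses), collapse = ", "), "\n")
  cat("  interannual trends (logit index): ",
      paste(sprintf("%s=%+.3f", x$provinces$province, x$responses$logit_index$trend),
            collapse = ", "), "\n")
  invisible(x)
}
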