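#' Convert a log/logit-scale slope to percent change per year
#'
#' Exact exponential conversion `100 (exp(slope) - 1)`. A slope of 0.01 per
#' year corresponds to approximately (but not exactly) a 1% change per year;
#' the approximation `100 * slope` agrees to the printed precision for the
#' small slopes typical here.
#'
#' @param slope Slope(s) per year on the log or logit scale.
#' @return Percent change per year.
#' @export
#' @examples
#' percent_per_year(0.01)   # 1.005
percent_per_year <- function(slope) {
  if (any(!is.finite(slope))) stop("slope must be finite")
  100 * (exp(slope) - 1)
}

#' Compound an annual percent rate over a horizon
#'
#' `100 ((1 + rate/100)^years - 1)`: +1% per year compounds to about +82%
#' over 60 years, and -2% per year to about -70%.
#'
#' @param annual_rate Percent change per year (> -100).
#' @param years Horizon in years (>= 0).
#' @return Total percent change over the horizon.
#' @export
#' @examples
#' compound_change(1, 60)    # 81.67
#' compound_change(-2, 60)   # -70.21
compound_change <- function(annual_rate, years) {
  if (any(annual_rate <= -100)) stop("annual_rate must be > -100")
  if (any(years < 0)) stop("years must be >= 0")
  100 * ((1 + annual_rate / 100)^years - 1)
}

#' Trend report: percent change per year and compounded change
#'
#' Summarizes the interannual trend posteriors of a fit as percent change
#' per year and total compounded change over a multi-decade horizon, with
#' 66% and 95% credible intervals transformed through the same exact
#' exponential formulas.
#'
#' @param fit A `plankton_fit`.
#' @param years Compounding horizon (default 60 years, matching a
#'   1960--2017-era record).
#' @return data.frame per province: slope quantiles, `pct_per_yr` (median),
#'   and compounded percent change with CI bounds.
#' @export
trend_report <- function(fit, years = 60) {
  s <- slope_summary(fit, parameters = "gamma")
  data.frame(
    province = s$province,
    response = fit$response,
    slope = s$q50,
    slope_q2.5 = s$q2.5, slope_q17 = s$q17,
    slope_q83 = s$q83, slope_q97.5 = s$q97.5,
    pct_per_yr = percent_per_year(s$q50),
    pct_per_yr_q2.5 = percent_per_year(s$q2.5),
    pct_per_yr_q97.5 = percent_per_year(s$q97.5),
    compounded_pct = compound_change(percent_per_year(s$q50), years),
    compounded_q2.5 = compound_change(percent_per_year(s$q2.5), years),
    compounded_q97.5 = compound_change(percent_per_year(s$q97.5), years),
    horizon_years = years,
    stringsAsFactors = FALSE
  )
}

#' Monthly climatology from a fitted model
#'
#' Posterior medians and 95% credible intervals of the twelve month effects
#' per province, plus the annual mean (mean of the twelve month-effect
#' medians).
#'
#' @param fit A `plankton_fit`.
#' @return data.frame with `province`, `month`, `q2.5`, `q50`, `q97.5`,
#'   `annual_mean`.
#' @export
monthly_climatology <- function(fit) {
  s <- slope_summary(fit, parameters = unname(fit$design$symbols[["month"]]))
  s <- s[order(s$province, s$index), ]
  ann <- tapply(s$q50, s$province, mean)
  data.frame(
    province = s$province, month = s$index,
    q2.5 = s$q2.5, q50 = s$q50, q97.5 = s$q97.5,
    annual_mean = as.numeric(ann[s$province]),
    stringsAsFactors = FALSE
  )
}
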