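#' Latitude band assignment
#'
#' Bands are half-open intervals `[k w, (k + 1) w)` anchored at the equator;
#' the band center is returned. With the default 2.5 degree width, latitude
#' 51.0 falls in `[50, 52.5)` and maps to 51.25.
#'
#' @param latitude Latitude(s) in degrees north (finite).
#' @param band_width Band width in degrees (> 0).
#' @return Band center latitude(s).
#' @export
#' @examples
#' assign_band(c(51, 50, 49.999))
assign_band <- function(latitude, band_width = 2.5) {
  if (any(!is.finite(latitude))) stop("latitude must be finite")
  if (band_width <= 0) stop("band_width must be > 0")
  floor(latitude / band_width) * band_width + band_width / 2
}

#' Decade label of a year
#'
#' Calendar decade: 1960--1969 map to 1960, and so on.
#'
#' @param year Integer year(s).
#' @return Integer decade label(s).
#' @export
decade_label <- function(year) {
  as.integer(10 * floor(year / 10))
}

#' Aggregate per-sample biomass into province x band x month x year bins
#'
#' Sums diatom (`q`) and dinoflagellate (`r`) biomass over all samples
#' falling in the same province, 2.5 degree latitude band, month and year;
#' longitude is discarded (bins span the full longitudinal extent of the
#' province). Output contains one row per populated bin, pre-imputation
#' (zeros possible).
#'
#' @param samples Per-sample biomass from [community_biomass()].
#' @param band_width Latitude band width in degrees.
#' @return data.frame with columns `province`, `latitude` (band center),
#'   `year`, `month`, `decade`, `q`, `r` (micrograms carbon).
#' @export
aggregate_bins <- function(samples, band_width = 2.5) {
  band <- assign_band(samples$latitude, band_width)
  key <- paste(samples$province, band, samples$year, samples$month, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    province = samples$province[first],
    latitude = band[first],
    year = samples$year[first],
    month = samples$month[first],
    stringsAsFactors = FALSE
  )
  out$decade <- decade_label(out$year)
  idx <- match(key, key[first])
  out$q <- as.numeric(rowsum(samples$diatom_ugC, idx)[, 1])
  out$r <- as.numeric(rowsum(samples$dino_ugC, idx)[, 1])
  ord <- order(out$province, out$latitude, out$year, out$month)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replace zero bin biomass by half the group-wide minimum
#'
#' For each functional group independently, a zero binned biomass is replaced
#' by 50% of the minimum positive binned biomass of that group over the whole
#' aggregated dataset (a half-detection-limit imputation). The diatom index
#' `p = q / (q + r)` and its logit `h` are computed after imputation, so both
#' are finite for every bin.
#'
#' @param bins Pre-imputation bins from [aggregate_bins()].
#' @return The bins with `q`, `r` imputed, logical flags `q_imputed`,
#'   `r_imputed`, and columns `p` and `h` added.
#' @export
impute_zeros <- function(bins) {
  floor_of <- function(x, group) {
    pos <- x[x > 0]
    if (length(pos) == 0) {
      stop("all binned ", group, " biomasses are zero; cannot impute")
    }
    0.5 * min(pos)
  }
  qf <- floor_of(bins$q, "diatom")
  rf <- floor_of(bins$r, "dinoflagellate")
  bins$q_imputed <- bins$q == 0
  bins$r_imputed <- bins$r == 0
  bins$q[bins$q_imputed] <- qf
  bins$r[bins$r_imputed] <- rf
  bins$p <- bins$q / (bins$q + bins$r)
  bins$h <- logit(bins$p)
  attr(bins, "imputation_floor") <- c(diatom = qf, dinoflagellate = rf)
  bins
}

#' Prepare analysis-ready bins from abundance records
#'
#' Chains carbon conversion, binning and zero imputation.
#'
#' @param records Abundance records.
#' @param traits Trait table.
#' @param band_width Latitude band width in degrees.
#' @return Imputed bins, see [impute_zeros()].
#' @export
prepare_bins <- function(records, traits, band_width = 2.5) {
  traits <- impute_missing_size(traits)
  samples <- community_biomass(records, traits)
  impute_zeros(aggregate_bins(samples, band_width))
}

#' Logit and inverse logit
#'
#' `logit(x) = ln(x / (1 - x))` maps (0, 1) onto the real line;
#' `inv_logit` is its inverse.
#'
#' @param x Proportion(s) strictly inside (0, 1) for `logit`; any real for
#'   `inv_logit`.
#' @return Transformed values.
#' @export
logit <- function(x) {
  if (any(x <= 0 | x >= 1)) stop("logit requires 0 < x < 1")
  log(x / (1 - x))
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  1 / (1 + exp(-x))
}
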