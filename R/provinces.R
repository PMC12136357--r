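#' Default biogeographic provinces
#'
#' Five North Atlantic provinces treated as categorical strata with declared
#' latitude spans (degrees north). The spans mimic the latitudinal extent of
#' the Longhurst provinces ARCT, SARC, NWCS, NADR and NECS but carry no
#' polygon geometry: the models use only the province label and the latitude
#' of each observation.
#'
#' @return A data.frame with columns `province`, `lat_min`, `lat_max`.
#' @export
#' @examples
#' default_provinces()
default_provinces <- function() {
  data.frame(
    province = c("ARCT", "SARC", "NADR", "NWCS", "NECS"),
    lat_min  = c(62.5, 55.0, 45.0, 37.5, 50.0),
    lat_max  = c(72.5, 65.0, 55.0, 47.5, 60.0),
    stringsAsFactors = FALSE
  )
}

#' Latitude band centers covering a province's declared span
#'
#' @param province_row One row of [default_provinces()].
#' @param band_width Band width in degrees latitude.
#' @return Numeric vector of band center latitudes.
#' @keywords internal
province_bands <- function(province_row, band_width = 2.5) {
  lo <- floor(province_row$lat_min / band_width) * band_width
  centers <- seq(lo + band_width / 2, province_row$lat_max, by = band_width)
  centers[centers > province_row$lat_min & centers < province_row$lat_max]
}
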