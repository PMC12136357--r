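#' Allometric cell volume to carbon coefficients
#'
#' Log-log power-law coefficients `log10(pg C) = a + b * log10(V um^3)` per
#' functional group. Defaults are the standard allometric fits for diatoms
#' and the general protist relation applied to dinoflagellates. They live in
#' configuration rather than code so alternative calibrations can be swapped
#' in without touching the pipeline.
#'
#' @return Named list of `c(a, b)` per group.
#' @export
carbon_coefficients <- function() {
  list(
    diatom = c(a = -0.541, b = 0.811),
    dinoflagellate = c(a = -0.665, b = 0.939)
  )
}

#' Carbon content of a cell from its volume
#'
#' Evaluates the group-specific allometric power law
#' `log10(pg C) = a + b log10(V)`.
#'
#' @param volume Cell volume(s) in um^3, > 0.
#' @param group Functional group per cell: `"diatom"` or `"dinoflagellate"`
#'   (recycled if length 1).
#' @param coefficients Coefficient list as from [carbon_coefficients()].
#'
#' @return Carbon per cell in pg C.
#' @export
#' @examples
#' cell_carbon(1000, "diatom")  # ~78 pg C
cell_carbon <- function(volume, group, coefficients = carbon_coefficients()) {
  if (any(!is.finite(volume) | volume <= 0)) stop("cell volume must be > 0")
  if (!all(group %in% names(coefficients))) {
    stop("unknown group: ", paste(setdiff(group, names(coefficients)), collapse = ", "))
  }
  if (length(group) == 1) group <- rep(group, length(volume))
  a <- vapply(coefficients, `[[`, numeric(1), "a")[group]
  b <- vapply(coefficients, `[[`, numeric(1), "b")[group]
  unname(10^(a + b * log10(volume)))
}

#' Impute per-cell carbon for taxa of unknown size
#'
#' Computes per-cell carbon for every taxon; a taxon with missing volume
#' receives the geometric mean (mean on the log scale) of the per-cell carbon
#' of all same-group taxa with known size. Imputation is done on the carbon
#' scale rather than the volume scale.
#'
#' @param traits Trait table with columns `taxon`, `group`, `volume_um3`
#'   (`NA` allowed).
#' @param coefficients Allometric coefficients, see [carbon_coefficients()].
#'
#' @return The trait table with added columns `carbon_pg` and `imputed_size`.
#' @export
impute_missing_size <- function(traits, coefficients = carbon_coefficients()) {
  traits$carbon_pg <- NA_real_
  traits$imputed_size <- is.na(traits$volume_um3)
  known <- !traits$imputed_size
  traits$carbon_pg[known] <- cell_carbon(
    traits$volume_um3[known], traits$group[known], coefficients
  )
  for (g in unique(traits$group[traits$imputed_size])) {
    donors <- traits$carbon_pg[known & traits$group == g]
    if (length(donors) == 0) {
      stop("cannot impute size for group '", g, "': no taxon with known size")
    }
    traits$carbon_pg[traits$imputed_size & traits$group == g] <-
      exp(mean(log(donors)))
  }
  traits
}

#' Per-sample functional-group carbon biomass
#'
#' Sums abundance times per-cell carbon over the taxa of each functional
#' group within each sample (province, latitude, longitude, year, month).
#' Samples where a group was not recorded get biomass 0 for that group.
#'
#' @param records Abundance records (columns `taxon`, `group`, `abundance`,
#'   `latitude`, `longitude`, `year`, `month`, `province`).
#' @param traits Trait table already carrying `carbon_pg`
#'   (see [impute_missing_size()]).
#'
#' @return data.frame with the sample key columns plus `diatom_ugC` and
#'   `dino_ugC` (micrograms carbon).
#' @export
community_biomass <- function(records, traits) {
  if (is.null(traits$carbon_pg)) traits <- impute_missing_size(traits)
  if (any(records$abundance < 0)) stop("abundances must be >= 0")
  if (any(!records$month %in% 1:12)) stop("month must be in 1..12")
  ti <- match(records$taxon, traits$taxon)
  if (anyNA(ti)) {
    stop("unknown taxon id: ",
         paste(unique(records$taxon[is.na(ti)]), collapse = ", "))
  }
  contrib_ugC <- records$abundance * traits$carbon_pg[ti] * 1e-6
  key <- paste(records$province, records$latitude, records$longitude,
               records$year, records$month, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    province = records$province[first],
    latitude = records$latitude[first],
    longitude = records$longitude[first],
    year = records$year[first],
    month = records$month[first],
    stringsAsFactors = FALSE
  )
  idx <- match(key, key[first])
  nbin <- sum(first)
  sum_group <- function(g) {
    sel <- records$group == g
    s <- numeric(nbin)
    agg <- rowsum(contrib_ugC[sel], idx[sel])
    s[as.integer(rownames(agg))] <- agg[, 1]
    s
  }
  out$diatom_ugC <- sum_group("diatom")
  out$dino_ugC <- sum_group("dinoflagellate")
  out
}
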