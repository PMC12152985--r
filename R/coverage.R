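#' Population coverage by travel-time band
#'
#' Sums the sub-group population per access band and expresses each band as a
#' percentage of the regional sub-group total. Percentages sum to 100 up to
#' floating-point rounding; a zero total yields missing percentages with a
#' warning.
#'
#' @param bands \linkS4class{GridRaster} of band indices
#'   (\code{\link{bandClassify}}).
#' @param pop \linkS4class{GridRaster} of sub-group persons on the same grid.
#' @param nBands number of bands reported (defaults to the maximum index
#'   present; pass \code{length(breaks) + 1} for a fixed layout).
#' @return \code{data.frame} with band, population, percent.
#' @examples
#' bands <- gridRaster(matrix(c(1, 1, 2, 4), 2), 100)
#' pop <- gridRaster(matrix(c(10, 20, 30, 40), 2), 100)
#' coverageByBand(bands, pop)
#' @export
coverageByBand <- function(bands, pop, nBands = NULL) {
  if (!.sameGrid(bands, pop)) stop("band and population grids do not match")
  b <- as.integer(bands@values)
  if (is.null(nBands)) nBands <- max(b, 1L)
  popSum <- vapply(seq_len(nBands),
                   function(k) sum(pop@values[b == k]), 0)
  total <- sum(pop@values)
  pct <- if (total > 0) 100 * popSum / total else {
    warning("zero total population; percentages undefined")
    rep(NA_real_, nBands)
  }
  data.frame(band = seq_len(nBands), population = popSum, percent = pct)
}

#' Facilities providing a service in a year, as travel-time sources
#'
#' Selects registry rows whose facility provided the indicator in the year
#' (caesarean sources are restricted to hospitals) and drops facilities
#' excluded from spatial analyses (\code{unresolved} QA status), when a QA
#' table is supplied.
#'
#' @param cube a \linkS4class{ProvisionCube}.
#' @param indicator service indicator.
#' @param year calendar year.
#' @param qa optional QA table from \code{\link{qaLocations}}.
#' @return registry subset (possibly empty) with x, y columns.
#' @export
serviceSources <- function(cube, indicator, year, qa = NULL) {
  reg <- cubeRegistry(cube)
  prov <- SummarizedExperiment::assay(cube, indicator)[, as.character(year)]
  keep <- prov & reg$type %in% .eligibleTypes(indicator)
  if (!is.null(qa)) {
    unresolved <- qa$facility_id[qa$status == "unresolved"]
    keep <- keep & !reg$facility_id %in% unresolved
  }
  reg[keep, , drop = FALSE]
}

#' Coverage trend over services and years
#'
#' The full downstream assembly: for each indicator and year, facilities
#' providing the service become travel-time sources on the friction surface,
#' travel times are banded, the year's projected sub-group population is
#' summed per band, and the long table is returned with a change column
#' (last-minus-first year percent within each indicator x band).
#'
#' @param cube a \linkS4class{ProvisionCube} (registry in \code{rowData}).
#' @param friction \linkS4class{GridRaster} from \code{\link{buildFriction}}.
#' @param basePop baseline population \linkS4class{GridRaster}.
#' @param projCfg a \linkS4class{ProjectionConfig}.
#' @param years years to cover (default all study years).
#' @param indicators indicators to cover (default all six).
#' @param breaks band boundaries in minutes.
#' @param qa optional QA table; unresolved facilities are not used as
#'   sources.
#' @param snapRadius metres, see \code{\link{cumulativeTravelTime}}.
#' @return \code{data.frame} with indicator, year, band, population, percent,
#'   and change (percent difference vs the first covered year, populated on
#'   the last year's rows).
#' @export
coverageTrend <- function(cube, friction, basePop, projCfg,
                          years = STUDY_YEARS,
                          indicators = SERVICE_INDICATORS,
                          breaks = c(30, 60, 120), qa = NULL,
                          snapRadius = 500) {
  nBands <- length(breaks) + 1L
  rows <- list()
  for (ind in indicators) {
    for (y in years) {
      src <- serviceSources(cube, ind, y, qa)
      if (nrow(src) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          indicator = ind, year = y, band = seq_len(nBands),
          population = NA_real_, percent = NA_real_)
        next
      }
      tt <- cumulativeTravelTime(friction, src, snapRadius = snapRadius,
                                 indicator = ind, year = y)
      bands <- bandClassify(tt, breaks)
      pop <- projectPopulation(basePop, projCfg, y)
      sub <- subgroupRaster(pop, projCfg, y, serviceSubgroup(ind))
      cov <- coverageByBand(bands, sub, nBands = nBands)
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, year = y, band = cov$band,
        population = cov$population, percent = cov$percent)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  yFirst <- min(years); yLast <- max(years)
  out$change <- NA_real_
  for (ind in indicators) {
    for (b in seq_len(nBands)) {
      p0 <- out$percent[out$indicator == ind & out$year == yFirst & out$band == b]
      p1 <- out$percent[out$indicator == ind & out$year == yLast & out$band == b]
      if (length(p0) && length(p1))
        out$change[out$indicator == ind & out$year == yLast & out$band == b] <-
          p1 - p0
    }
  }
  out
}
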