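#' Configure population projection
#'
#' Annual geometric growth applied to a gridded baseline: forward from the
#' baseline year as \eqn{P_y = P_{y-1}(1 + r_y/100)} and backward as the exact
#' inverse, \eqn{P_y = P_{y+1}/(1 + r_{y+1}/100)}, compounded year by year.
#' Age-sex sub-group proportions are applied uniformly in space, per year.
#'
#' @param baselineYear census baseline year of the input raster.
#' @param growthRatePct annual growth rate in percent; scalar, or a vector
#'   named by year where the rate for year y governs the y-1 -> y step.
#' @param subgroupProps either a named vector of fractions (\code{wocba},
#'   \code{under5}) used for every year, or a list of such vectors named by
#'   year.
#' @return A \linkS4class{ProjectionConfig}.
#' @examples
#' projectionConfig(growthRatePct = 2)
#' @export
projectionConfig <- function(baselineYear = 2021L, growthRatePct = 2,
                             subgroupProps = c(wocba = 0.24, under5 = 0.13)) {
  if (!is.list(subgroupProps))
    subgroupProps <- stats::setNames(
      rep(list(subgroupProps), length(STUDY_YEARS)), STUDY_YEARS)
  new("ProjectionConfig", baselineYear = as.integer(baselineYear),
      growthRatePct = growthRatePct, subgroupProps = subgroupProps)
}

# growth rate governing the (y-1) -> y step
.rateFor <- function(cfg, year) {
  r <- cfg@growthRatePct
  if (!is.null(names(r))) {
    if (!as.character(year) %in% names(r))
      stop("no growth rate configured for year ", year)
    r <- r[[as.character(year)]]
  }
  if (1 + r / 100 <= 0) stop("growth rate must exceed -100 percent")
  r
}

#' Project the gridded population to a target year
#'
#' Cell-wise uniform scaling: the spatial pattern (and cell rank order) of the
#' baseline raster is preserved exactly, only the regional total changes by
#' the compounded growth factor.
#'
#' @param baseline \linkS4class{GridRaster} of persons for
#'   \code{cfg@baselineYear}.
#' @param cfg a \linkS4class{ProjectionConfig}.
#' @param targetYear year within the study window.
#' @return A \linkS4class{GridRaster} of persons for \code{targetYear}.
#' @examples
#' base <- gridRaster(matrix(1000, 2, 2), 100)
#' sum(gridValues(projectPopulation(base, projectionConfig(), 2022)))
#' @export
projectPopulation <- function(baseline, cfg, targetYear) {
  targetYear <- as.integer(targetYear)
  if (targetYear < min(STUDY_YEARS) || targetYear > max(STUDY_YEARS))
    stop("targetYear must lie in ", min(STUDY_YEARS), "-", max(STUDY_YEARS))
  b <- cfg@baselineYear
  factorTotal <- 1
  if (targetYear > b) {
    for (y in seq(b + 1L, targetYear))
      factorTotal <- factorTotal * (1 + .rateFor(cfg, y) / 100)
  } else if (targetYear < b) {
    for (y in seq(b, targetYear + 1L))
      factorTotal <- factorTotal / (1 + .rateFor(cfg, y) / 100)
  }
  gridRaster(baseline@values * factorTotal, baseline@cellSize,
             baseline@origin)
}

#' Derive a population sub-group raster
#'
#' Multiplies the year's population raster by the configured age-sex
#' proportion: \code{total} is the identity, \code{wocba} women of
#' childbearing age (15-49), \code{under5} children under five.
#'
#' @param pop \linkS4class{GridRaster} of total persons for \code{year}.
#' @param cfg a \linkS4class{ProjectionConfig}.
#' @param year calendar year (selects the proportion set).
#' @param subgroup one of \code{"total"}, \code{"wocba"}, \code{"under5"}.
#' @return A \linkS4class{GridRaster} of sub-group persons.
#' @export
subgroupRaster <- function(pop, cfg, year, subgroup = c("total", "wocba",
                                                        "under5")) {
  subgroup <- match.arg(subgroup)
  if (subgroup == "total") return(pop)
  props <- cfg@subgroupProps[[as.character(year)]]
  if (is.null(props) || !subgroup %in% names(props))
    stop("no ", subgroup, " proportion configured for year ", year)
  gridRaster(pop@values * props[[subgroup]], pop@cellSize, pop@origin)
}

#' Sub-group targeted by each service indicator
#'
#' Outpatient and malaria serve the general population, antenatal, birth and
#' caesarean care women of childbearing age, and first-dose pentavalent
#' vaccination children under five.
#'
#' @param indicator one of \code{SERVICE_INDICATORS} (or missing for the full
#'   map).
#' @return sub-group name, or the full named map.
#' @export
serviceSubgroup <- function(indicator) {
  map <- c(outpatient = "total", malaria = "total", antenatal = "wocba",
           birth = "wocba", caesarean = "wocba", pentavalent1 = "under5")
  if (missing(indicator)) return(map)
  if (!indicator %in% names(map)) stop("unknown indicator: ", indicator)
  map[[indicator]]
}
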