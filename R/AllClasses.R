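#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib hmisaccess, .registration = TRUE
NULL

#' Service indicators tracked by the package
#'
#' The six routine service indicators analysed: outpatient attendance, malaria
#' treatment, antenatal registration, facility births, caesarean births and
#' first-dose pentavalent vaccination (proxy for childhood immunisation).
#' @export
SERVICE_INDICATORS <- c("outpatient", "malaria", "antenatal", "birth",
                        "caesarean", "pentavalent1")

#' Facility types and ownership categories
#' @rdname SERVICE_INDICATORS
#' @export
FACILITY_TYPES <- c("CHPS", "HealthCentre", "Hospital", "MaternityHome")

#' @rdname SERVICE_INDICATORS
#' @export
OWNERSHIP_LEVELS <- c("Government", "FaithBased", "Private")

#' @rdname SERVICE_INDICATORS
#' @export
STUDY_YEARS <- 2016:2022

#' Functional classes assigned to facilities
#'
#' The five top-level spatio-temporal groups (closed, newly operational, no
#' service, oscillating, existing) with existing sub-categorised by service-set
#' trajectory, plus a residual \code{other_intermittent} class for facilities
#' operational in the first and last year but with a non-operational year in
#' between (the five groups alone are not exhaustive).
#' @export
FUNCTIONAL_CLASSES <- c("closed", "newly_operational", "no_service",
                        "oscillating", "existing_unchanged",
                        "existing_increased", "existing_decreased",
                        "existing_varying", "other_intermittent")

#' GridRaster: a planar single-band raster
#'
#' Minimal raster container on a regular planar metric grid. Row 1 of
#' \code{values} is the northernmost row; \code{origin} is the lower-left
#' corner of the grid in metres.
#'
#' @slot values numeric matrix of cell values.
#' @slot cellSize cell edge length in metres.
#' @slot origin numeric length-2, (x, y) of the lower-left grid corner.
#' @export
setClass("GridRaster",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"),
  prototype(values = matrix(0, 1, 1), cellSize = 100, origin = c(0, 0)))

setValidity("GridRaster", function(object) {
  msg <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite coordinates")
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' TravelTimeSurface: minutes to the nearest providing facility
#'
#' A \linkS4class{GridRaster} of travel time in minutes, tagged with the
#' service indicator and year it was computed for. Unreachable cells are
#' \code{Inf}; source cells are 0.
#'
#' @slot indicator service indicator name.
#' @slot year calendar year of the facility source set.
#' @export
setClass("TravelTimeSurface", contains = "GridRaster",
  representation(indicator = "character", year = "integer"),
  prototype(indicator = NA_character_, year = NA_integer_))

#' SpeedConfig: multimodal travel-speed table
#'
#' Travel speeds feeding the friction surface: walking speeds (km/h) per
#' land-cover class, moderated by slope via Tobler's hiking function, and
#' mechanised speeds (km/h) per road class (not slope-adjusted). Water is
#' impassable unless a road (bridge) crosses it.
#'
#' @slot walkKmh named numeric, walking speed per land-cover class.
#' @slot roadKmh named numeric, speed per road class.
#' @slot waterImpassable logical, treat water cells as barriers.
#' @export
setClass("SpeedConfig",
  representation(walkKmh = "numeric", roadKmh = "numeric",
                 waterImpassable = "logical"),
  prototype(waterImpassable = TRUE))

setValidity("SpeedConfig", function(object) {
  msg <- character()
  if (length(object@walkKmh) == 0L || is.null(names(object@walkKmh)))
    msg <- c(msg, "walkKmh must be a named vector of land-cover speeds")
  if (any(!is.finite(object@walkKmh)) || any(object@walkKmh <= 0))
    msg <- c(msg, "walking speeds must be positive and finite")
  if (length(object@roadKmh) &&
      (any(!is.finite(object@roadKmh)) || any(object@roadKmh <= 0)))
    msg <- c(msg, "road speeds must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' ProvisionCube: facility x year x indicator service-provision tensor
#'
#' A \linkS4class{SummarizedExperiment} with facilities as rows, study years as
#' columns and one logical assay per service indicator: \code{TRUE} when the
#' facility reported a positive count for that indicator in that year. The
#' facility registry is carried in \code{rowData}. A facility is
#' \emph{operational} in a year if any indicator is \code{TRUE} that year.
#'
#' @export
setClass("ProvisionCube", contains = "SummarizedExperiment")

setValidity("ProvisionCube", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(SERVICE_INDICATORS %in% a))
    msg <- c(msg, "one logical assay per service indicator is required")
  for (nm in intersect(a, SERVICE_INDICATORS))
    if (!is.logical(SummarizedExperiment::assay(object, nm)))
      msg <- c(msg, sprintf("assay '%s' must be logical", nm))
  if (length(msg)) msg else TRUE
})

#' RegionScenario: configuration of the synthetic-region generator
#'
#' All knobs of the seeded synthetic study region: grid dimensions, facility
#' composition, functional-archetype mix, coordinate-error injection rate,
#' population size and growth, and sub-group proportions.
#'
#' @slot nRows,nCols grid dimensions in cells (>= 10).
#' @slot cellSize cell edge in metres.
#' @slot seed integer RNG seed; every generator is fully deterministic in it.
#' @slot nFacilities number of facilities to place.
#' @slot typeMix named probability vector over facility types.
#' @slot ownershipMix either a named probability vector over ownership, or a
#'   type x ownership matrix of type-conditional ownership probabilities.
#' @slot archetypeMix named probability vector over functional archetypes.
#' @slot coordErrorRate fraction of facilities with corrupted published
#'   coordinates.
#' @slot totalPopulation persons in the baseline-year population raster.
#' @slot growthRatePct annual population growth rate, percent.
#' @slot subgroupProps named fractions for \code{wocba} and \code{under5}.
#' @slot nDistricts number of rectangular districts partitioning the region.
#' @slot waterEnabled whether a river barrier is generated.
#' @export
setClass("RegionScenario",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 seed = "integer", nFacilities = "integer",
                 typeMix = "numeric", ownershipMix = "ANY",
                 archetypeMix = "numeric", coordErrorRate = "numeric",
                 totalPopulation = "numeric", growthRatePct = "numeric",
                 subgroupProps = "numeric", nDistricts = "integer",
                 waterEnabled = "logical"))

setValidity("RegionScenario", function(object) {
  msg <- character()
  probsOk <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)
  if (object@nRows < 10L || object@nCols < 10L)
    msg <- c(msg, "grid must be at least 10 x 10 cells")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
  if (!probsOk(object@typeMix) ||
      !setequal(names(object@typeMix), FACILITY_TYPES))
    msg <- c(msg, "typeMix must be probabilities over the four facility types summing to 1")
  om <- object@ownershipMix
  if (is.matrix(om)) {
    if (!setequal(rownames(om), FACILITY_TYPES) ||
        !setequal(colnames(om), OWNERSHIP_LEVELS) ||
        any(abs(rowSums(om) - 1) > 1e-9) || any(om < 0))
      msg <- c(msg, "ownershipMix matrix rows must be per-type probabilities summing to 1")
  } else if (!probsOk(om) || !setequal(names(om), OWNERSHIP_LEVELS)) {
    msg <- c(msg, "ownershipMix must be probabilities over ownership levels summing to 1")
  }
  if (!probsOk(object@archetypeMix) ||
      !all(names(object@archetypeMix) %in% setdiff(FUNCTIONAL_CLASSES, "other_intermittent")))
    msg <- c(msg, "archetypeMix must be probabilities over known archetypes summing to 1")
  if (object@coordErrorRate < 0 || object@coordErrorRate > 1)
    msg <- c(msg, "coordErrorRate must be in [0, 1]")
  if (object@totalPopulation <= 0) msg <- c(msg, "totalPopulation must be positive")
  if (1 + object@growthRatePct / 100 <= 0)
    msg <- c(msg, "growthRatePct must exceed -100")
  if (!all(c("wocba", "under5") %in% names(object@subgroupProps)) ||
      any(object@subgroupProps < 0) || any(object@subgroupProps > 1))
    msg <- c(msg, "subgroupProps must give wocba and under5 fractions in [0, 1]")
  if (object@nDistricts < 1L) msg <- c(msg, "nDistricts must be at least 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticRegion: a generated study region and HMIS archive
#'
#' Bundle of all layers a scenario generates: terrain, roads, water,
#' population, districts, the facility registry (with both true and published
#' coordinates), seven years of service records and the ground-truth labels
#' (archetype and injected coordinate-error kind) enabling recovery tests.
#'
#' @slot scenario the generating \linkS4class{RegionScenario}.
#' @slot dem,landcover,population \linkS4class{GridRaster} layers.
#' @slot roads,water lists of polyline features (see \code{\link{readGeoJSON}}).
#' @slot districts named list of polygon rings.
#' @slot registry published facility registry \code{data.frame}.
#' @slot records long service-record \code{data.frame}.
#' @slot groundTruth per-facility truth \code{data.frame} (archetype,
#'   coordinate-error kind, true coordinates).
#' @export
setClass("SyntheticRegion",
  representation(scenario = "RegionScenario", dem = "GridRaster",
                 landcover = "GridRaster", population = "GridRaster",
                 roads = "list", water = "list", districts = "list",
                 registry = "data.frame", records = "data.frame",
                 groundTruth = "data.frame"))

#' ProjectionConfig: population projection settings
#'
#' @slot baselineYear census baseline year of the input raster (default 2021).
#' @slot growthRatePct annual growth rate in percent; a scalar applied to all
#'   years or a vector named by year (rate for year y governs the y-1 -> y step).
#' @slot subgroupProps list mapping year -> named fractions (\code{wocba},
#'   \code{under5}); \code{total} is implicitly 1.
#' @export
setClass("ProjectionConfig",
  representation(baselineYear = "integer", growthRatePct = "numeric",
                 subgroupProps = "list"))

setValidity("ProjectionConfig", function(object) {
  msg <- character()
  if (any(1 + object@growthRatePct / 100 <= 0))
    msg <- c(msg, "growth rates must exceed -100 percent")
  if (length(msg)) msg else TRUE
})
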