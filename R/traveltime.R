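#' Default multimodal speed table
#'
#' Walking speeds per land-cover class and mechanised speeds per road class,
#' in km/h. These are package defaults for scenario work, not measured
#' values: real analyses should substitute locally tracked speeds.
#'
#' @param walkKmh named walking speeds per land-cover class.
#' @param roadKmh named speeds per road class.
#' @param waterImpassable treat water cells as barriers.
#' @return A \linkS4class{SpeedConfig}.
#' @examples
#' speedConfig()
#' @export
speedConfig <- function(walkKmh = c(grassland = 5, cropland = 4,
                                    dense_vegetation = 2, builtup = 5),
                        roadKmh = c(primary = 80, secondary = 40,
                                    tertiary = 20),
                        waterImpassable = TRUE) {
  new("SpeedConfig", walkKmh = walkKmh, roadKmh = roadKmh,
      waterImpassable = waterImpassable)
}

setMethod("show", "SpeedConfig", function(object) {
  cat("SpeedConfig (km/h)\n  walking: ",
      paste(names(object@walkKmh), object@walkKmh, sep = "=", collapse = ", "),
      "\n  roads:   ",
      paste(names(object@roadKmh), object@roadKmh, sep = "=", collapse = ", "),
      "\n  water impassable: ", object@waterImpassable, "\n", sep = "")
  invisible(object)
})

#' Read a speed table from YAML
#'
#' Expects top-level keys \code{walking} (land-cover class -> km/h),
#' \code{roads} (road class -> km/h) and optional \code{water_impassable}.
#'
#' @param path YAML file path.
#' @return A \linkS4class{SpeedConfig}.
#' @export
readSpeedConfig <- function(path) {
  y <- yaml::read_yaml(path)
  speedConfig(walkKmh = unlist(y$walking), roadKmh = unlist(y$roads),
              waterImpassable = if (is.null(y$water_impassable)) TRUE
                                else isTRUE(y$water_impassable))
}

#' Tobler's hiking function, normalised to flat ground
#'
#' \eqn{f(s) = \exp(-3.5\,|s + 0.05|)\, /\, \exp(-3.5 \times 0.05)}: the
#' classic anisotropic hiking speed curve applied isotropically to the slope
#' magnitude and rescaled so flat terrain has factor 1. The factor
#' multiplies the land-cover walking speed; the maximum (about 1.19) occurs
#' on a gentle -5\% grade.
#'
#' @param slope dimensionless rise/run (may be a vector or matrix).
#' @return multiplicative speed factor, same shape as \code{slope}.
#' @examples
#' toblerFactor(0)      # 1
#' toblerFactor(-0.05)  # exp(0.175), the maximum
#' @export
toblerFactor <- function(slope) {
  exp(-3.5 * abs(slope + 0.05)) / exp(-3.5 * 0.05)
}

#' Build the multimodal friction surface
#'
#' Per-cell traversal cost in seconds per metre. Walking speed comes from the
#' land-cover class, moderated by \code{\link{toblerFactor}} of the local
#' slope; water cells are impassable (\code{Inf}); road cells override both
#' (a road crossing water is a bridge) with their class speed, not
#' slope-adjusted (mechanised travel).
#'
#' @param landcover \linkS4class{GridRaster} of legend classes.
#' @param dem \linkS4class{GridRaster} of elevation, metres.
#' @param roads list of polyline features with a \code{speed_class} property
#'   (or \code{NULL} for none).
#' @param water list of polyline/polygon features rasterised as barriers (or
#'   \code{NULL}).
#' @param cfg a \linkS4class{SpeedConfig}.
#' @return A \linkS4class{GridRaster} of seconds per metre.
#' @export
buildFriction <- function(landcover, dem, roads = NULL, water = NULL,
                          cfg = speedConfig()) {
  validObject(cfg)
  stopifnot(.sameGrid(landcover, dem))
  lc <- landcover@values
  classes <- sort(unique(as.vector(lc)))
  legend <- LANDCOVER_CLASSES[match(classes, LANDCOVER_CLASSES)]
  if (anyNA(legend))
    stop("land-cover class(es) outside the legend: ",
         paste(setdiff(classes, LANDCOVER_CLASSES), collapse = ", "))
  missingSpeed <- setdiff(names(legend), names(cfg@walkKmh))
  if (length(missingSpeed))
    stop("no walking speed configured for land-cover class(es): ",
         paste(missingSpeed, collapse = ", "))
  speed <- matrix(NA_real_, nrow(lc), ncol(lc))
  for (nm in names(legend))
    speed[lc == LANDCOVER_CLASSES[[nm]]] <- cfg@walkKmh[[nm]]
  speed <- speed * toblerFactor(slopeRaster(dem)@values)
  if (!is.null(water) && length(water) && cfg@waterImpassable) {
    wmask <- rasterizeLines(water, landcover, value = 1)@values > 0
    speed[wmask] <- 0
  }
  if (!is.null(roads) && length(roads)) {
    missingRoad <- setdiff(
      unique(vapply(roads, function(f) as.character(f$properties$speed_class), "")),
      names(cfg@roadKmh))
    if (length(missingRoad))
      stop("no speed configured for road class(es): ",
           paste(missingRoad, collapse = ", "))
    for (f in roads) {
      rmask <- rasterizeLines(list(f), landcover, value = 1)@values > 0
      speed[rmask] <- cfg@roadKmh[[f$properties$speed_class]]
    }
  }
  cost <- 3600 / (speed * 1000)   # km/h -> s/m
  cost[speed == 0] <- Inf
  gridRaster(cost, landcover@cellSize, landcover@origin)
}

#' Least-cost travel time to the nearest source facility
#'
#' Exact multi-source shortest path over the 8-connected grid: the step time
#' between adjacent cells is the step length (cell size orthogonally, times
#' \eqn{\sqrt 2} diagonally) multiplied by the mean of the two cells'
#' per-metre costs. Sources on impassable cells are snapped to the nearest
#' finite-cost cell within \code{snapRadius} metres, else dropped with a
#' warning.
#'
#' @param friction \linkS4class{GridRaster} of seconds per metre
#'   (\code{Inf} = impassable).
#' @param sources two-column matrix of source (x, y) coordinates, or a
#'   registry-like \code{data.frame} with \code{x}, \code{y} columns.
#' @param snapRadius metres; default 500.
#' @param indicator,year metadata tags for the resulting surface.
#' @return A \linkS4class{TravelTimeSurface} in minutes (\code{Inf} where
#'   unreachable).
#' @export
cumulativeTravelTime <- function(friction, sources, snapRadius = 500,
                                 indicator = NA_character_,
                                 year = NA_integer_) {
  xy <- if (is.data.frame(sources)) cbind(sources$x, sources$y)
        else matrix(as.numeric(sources), ncol = 2)
  cells <- cellFromXY(friction, xy)
  off <- is.na(cells[, 1])
  if (any(off)) {
    warning(sum(off), " source(s) outside the grid dropped")
    cells <- cells[!off, , drop = FALSE]
  }
  if (nrow(cells) == 0L) stop("no usable source")
  cost <- friction@values
  maxStep <- max(0L, as.integer(ceiling(snapRadius / friction@cellSize)))
  snapped <- t(apply(cells, 1, function(rc) .snapCell(cost, rc, maxStep)))
  lost <- is.na(snapped[, 1])
  if (any(lost))
    warning(sum(lost), " source(s) on impassable cells beyond the snap radius dropped")
  snapped <- snapped[!lost, , drop = FALSE]
  if (nrow(snapped) == 0L) stop("no usable source on a finite-cost cell")
  secs <- .dijkstraGrid(cost, snapped, friction@cellSize)
  new("TravelTimeSurface", values = secs / 60, cellSize = friction@cellSize,
      origin = friction@origin, indicator = indicator,
      year = as.integer(year))
}

# nearest finite-cost cell within maxStep Chebyshev rings; NA if none
.snapCell <- function(cost, rc, maxStep) {
  if (is.finite(cost[rc[1], rc[2]])) return(rc)
  nr <- nrow(cost); nc <- ncol(cost)
  for (radius in seq_len(maxStep)) {
    rows <- max(1, rc[1] - radius):min(nr, rc[1] + radius)
    cols <- max(1, rc[2] - radius):min(nc, rc[2] + radius)
    ring <- expand.grid(row = rows, col = cols)
    ring <- ring[pmax(abs(ring$row - rc[1]), abs(ring$col - rc[2])) == radius, ]
    fin <- ring[is.finite(cost[cbind(ring$row, ring$col)]), , drop = FALSE]
    if (nrow(fin)) {
      d2 <- (fin$row - rc[1])^2 + (fin$col - rc[2])^2
      best <- fin[which.min(d2), ]
      return(c(best$row, best$col))
    }
  }
  c(NA_integer_, NA_integer_)
}

#' Classify travel times into access bands
#'
#' Default bands: [0, 30], (30, 60], (60, 120] and (120, Inf] minutes —
#' boundary values belong to the lower band ("within 30 minutes" is
#' inclusive). Unreachable cells fall in the last band.
#'
#' @param tt a \linkS4class{TravelTimeSurface} (or any GridRaster of
#'   minutes).
#' @param breaks strictly increasing band boundaries, minutes.
#' @return A \linkS4class{GridRaster} of integer band indices (1-based).
#' @examples
#' r <- gridRaster(matrix(c(10, 30, 30.01, Inf), 2), 100)
#' gridValues(bandClassify(r))
#' @export
bandClassify <- function(tt, breaks = c(30, 60, 120)) {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  v <- tt@values
  band <- matrix(1L + findInterval(v, breaks, left.open = TRUE),
                 nrow(v), ncol(v))
  band[is.infinite(v)] <- length(breaks) + 1L
  gridRaster(band, tt@cellSize, tt@origin)
}

#' Change in travel time between two years
#'
#' Cell-wise later-minus-earlier difference. Cells unreachable in both years
#' are missing (\code{NA}); cells whose reachability changed are also
#' returned as \code{NA} in the difference but flagged in the
#' \code{"reachability"} attribute (\code{"gained"}/\code{"lost"}).
#'
#' @param ttEarlier,ttLater \linkS4class{TravelTimeSurface}s on the same grid
#'   for the same service.
#' @return A \linkS4class{GridRaster} of signed minutes with a
#'   \code{reachability} attribute matrix (levels both/gained/lost/neither).
#' @export
travelTimeChange <- function(ttEarlier, ttLater) {
  if (!.sameGrid(ttEarlier, ttLater)) stop("travel-time grids do not match")
  e <- ttEarlier@values; l <- ttLater@values
  change <- l - e
  reach <- matrix("both", nrow(e), ncol(e))
  reach[is.infinite(e) & is.infinite(l)] <- "neither"
  reach[is.infinite(e) & is.finite(l)] <- "gained"
  reach[is.finite(e) & is.infinite(l)] <- "lost"
  change[reach != "both"] <- NA_real_
  out <- gridRaster(change, ttEarlier@cellSize, ttEarlier@origin)
  attr(out@values, "reachability") <- reach
  out
}
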