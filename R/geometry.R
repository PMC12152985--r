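#' Point-in-polygon test
#'
#' Thin wrapper around \code{mgcv::in.out} for a single polygon ring.
#'
#' @param ring two-column matrix of ring vertices (closed or open).
#' @param xy two-column matrix of points.
#' @return logical vector, \code{TRUE} for points inside the ring.
#' @export
pointInPolygon <- function(ring, xy) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ]))
    ring <- rbind(ring, ring[1, ])
  xy <- matrix(as.numeric(xy), ncol = 2)
  mgcv::in.out(ring, xy)
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each point to any edge of the ring.
#'
#' @inheritParams pointInPolygon
#' @return numeric vector of distances in the ring's units.
#' @export
distanceToBoundary <- function(ring, xy) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ]))
    ring <- rbind(ring, ring[1, ])
  xy <- matrix(as.numeric(xy), ncol = 2)
  n <- nrow(ring) - 1L
  d <- rep(Inf, nrow(xy))
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      di <- sqrt((xy[, 1] - a[1])^2 + (xy[, 2] - a[2])^2)
    } else {
      t <- pmin(1, pmax(0, ((xy[, 1] - a[1]) * ab[1] +
                            (xy[, 2] - a[2]) * ab[2]) / len2))
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      di <- sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
    }
    d <- pmin(d, di)
  }
  d
}

# Length of the part of segment (a, b) inside an axis-aligned cell rectangle,
# by Liang-Barsky clipping. Used by the rasteriser oracle and exported for it.
.segmentClipLength <- function(a, b, xmin, xmax, ymin, ymax) {
  d <- b - a
  t0 <- 0; t1 <- 1
  for (k in 1:2) {
    lo <- if (k == 1) xmin else ymin
    hi <- if (k == 1) xmax else ymax
    if (d[k] == 0) {
      if (a[k] < lo || a[k] > hi) return(0)
    } else {
      ta <- (lo - a[k]) / d[k]; tb <- (hi - a[k]) / d[k]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

#' Rasterise polylines onto a grid
#'
#' Exact grid traversal: a cell is marked when a segment has positive-length
#' intersection with its interior. Crossing parameters at every grid line are
#' collected and interval midpoints assign cells, so grazing corner touches
#' (zero length in the cell) are not marked.
#'
#' @param features list of polyline features, each with a \code{coords}
#'   two-column matrix (as returned by \code{\link{readGeoJSON}}), or a single
#'   coordinate matrix.
#' @param template \linkS4class{GridRaster} defining the target grid.
#' @param value value to burn in, or the name of a property to burn (e.g.
#'   \code{"speed_class"}); the background is \code{background}.
#' @param background background cell value.
#' @return A \linkS4class{GridRaster}.
#' @export
rasterizeLines <- function(features, template, value = 1, background = 0) {
  if (is.matrix(features)) features <- list(list(coords = features))
  d <- dim(template@values); cs <- template@cellSize; o <- template@origin
  out <- matrix(background, d[1], d[2])
  for (f in features) {
    co <- as.matrix(f$coords)
    burn <- if (is.character(value)) f$properties[[value]] else value
    if (is.null(burn)) stop("feature lacks property '", value, "'")
    for (i in seq_len(nrow(co) - 1L)) {
      a <- co[i, ]; b <- co[i + 1, ]
      dx <- b[1] - a[1]; dy <- b[2] - a[2]
      segLen <- sqrt(dx^2 + dy^2)
      if (segLen == 0) next
      ts <- c(0, 1)
      gridKs <- function(lo, hi, orig) {
        from <- ceiling((lo - orig) / cs); to <- floor((hi - orig) / cs)
        if (from > to) numeric() else seq(from, to)
      }
      if (dx != 0) {
        ks <- gridKs(min(a[1], b[1]), max(a[1], b[1]), o[1])
        ts <- c(ts, (o[1] + ks * cs - a[1]) / dx)
      }
      if (dy != 0) {
        ks <- gridKs(min(a[2], b[2]), max(a[2], b[2]), o[2])
        ts <- c(ts, (o[2] + ks * cs - a[2]) / dy)
      }
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      if (length(ts) < 2) next
      mid <- (ts[-1] + ts[-length(ts)]) / 2
      keep <- (ts[-1] - ts[-length(ts)]) * segLen > 1e-9
      mid <- mid[keep]
      if (!length(mid)) next
      cells <- cellFromXY(template, cbind(a[1] + mid * dx, a[2] + mid * dy))
      ok <- !is.na(cells[, 1])
      out[cells[ok, , drop = FALSE]] <- burn
    }
  }
  gridRaster(out, cs, o)
}

#' Rasterise polygons onto a grid by cell-centre containment
#'
#' @param rings named list of polygon rings (two-column matrices).
#' @param template \linkS4class{GridRaster} defining the grid.
#' @param values value per ring (defaults to 1..n), burned where the cell
#'   centre falls inside.
#' @param background background value.
#' @return A \linkS4class{GridRaster}.
#' @export
rasterizePolygons <- function(rings, template, values = seq_along(rings),
                              background = 0) {
  d <- dim(template@values)
  cells <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  xy <- xyFromCell(template, cells)
  out <- matrix(background, d[1], d[2])
  for (i in seq_along(rings)) {
    inside <- pointInPolygon(rings[[i]], xy)
    out[cells[inside, , drop = FALSE]] <- values[i]
  }
  gridRaster(out, template@cellSize, template@origin)
}

#' Read and write simple GeoJSON feature collections
#'
#' Supports the vector layers the pipeline exchanges: LineString and Polygon
#' features with flat properties, on the planar working grid. Geometry
#' coordinates are (x, y) metre pairs.
#'
#' @param path file path.
#' @return \code{readGeoJSON}: a list of features, each a list with
#'   \code{type}, \code{coords} (two-column matrix; for polygons the outer
#'   ring) and \code{properties} (named list).
#' @export
readGeoJSON <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(g$features, function(f) {
    geom <- f$geometry
    co <- geom$coordinates
    m <- switch(geom$type,
      LineString = do.call(rbind, lapply(co, function(p) unlist(p)[1:2])),
      Polygon = do.call(rbind, lapply(co[[1]], function(p) unlist(p)[1:2])),
      stop("unsupported geometry type: ", geom$type))
    colnames(m) <- c("x", "y")
    list(type = geom$type, coords = m,
         properties = lapply(f$properties, identity))
  })
}

#' @rdname readGeoJSON
#' @param features list of features as returned by \code{readGeoJSON}.
#' @export
writeGeoJSON <- function(features, path) {
  feats <- lapply(features, function(f) {
    co <- lapply(seq_len(nrow(f$coords)),
                 function(i) as.numeric(f$coords[i, 1:2]))
    geom <- if (identical(f$type, "Polygon")) {
      list(type = "Polygon", coordinates = list(co))
    } else {
      list(type = "LineString", coordinates = co)
    }
    props <- if (length(f$properties)) f$properties else stats::setNames(list(), character())
    list(type = "Feature", geometry = geom, properties = props)
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
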