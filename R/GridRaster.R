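#' Construct a GridRaster
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param cellSize cell edge length, metres.
#' @param origin (x, y) of the lower-left corner, metres.
#' @return A \linkS4class{GridRaster}.
#' @examples
#' r <- gridRaster(matrix(1:12, 3, 4), cellSize = 100)
#' gridDim(r)
#' @export
gridRaster <- function(values, cellSize = 100, origin = c(0, 0)) {
  new("GridRaster", values = as.matrix(values), cellSize = cellSize,
      origin = as.numeric(origin))
}

#' @rdname gridRaster
#' @param x a GridRaster.
#' @export
gridValues <- function(x) x@values

#' @rdname gridRaster
#' @export
cellSize <- function(x) x@cellSize

#' @rdname gridRaster
#' @export
gridDim <- function(x) dim(x@values)

#' @rdname gridRaster
#' @export
gridOrigin <- function(x) x@origin

setMethod("show", "GridRaster", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("%s: %d x %d cells @ %g m, origin (%g, %g)\n",
              class(object), d[1], d[2], object@cellSize,
              object@origin[1], object@origin[2]))
  if (length(v))
    cat(sprintf("  finite values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
  invisible(object)
})

setMethod("show", "TravelTimeSurface", function(object) {
  callNextMethod()
  cat(sprintf("  service '%s', year %d; unreachable cells: %d\n",
              object@indicator, object@year, sum(is.infinite(object@values))))
  invisible(object)
})

#' @rdname gridRaster
#' @export
serviceIndicator <- function(x) x@indicator

#' @rdname gridRaster
#' @export
surfaceYear <- function(x) x@year

.sameGrid <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@cellSize, b@cellSize)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

#' Convert between cell indices and planar coordinates
#'
#' Cell (row, col) centres: row 1 is the top (north) row. Points on a cell
#' boundary belong to the cell to the right/above in index order, except the
#' outer edge which is clamped inward.
#'
#' @param r a \linkS4class{GridRaster} defining the grid.
#' @param xy two-column matrix of (x, y) coordinates.
#' @return \code{cellFromXY}: two-column integer matrix (row, col), \code{NA}
#'   for points outside the grid. \code{xyFromCell}: matrix of cell-centre
#'   coordinates.
#' @export
cellFromXY <- function(r, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  d <- dim(r@values); cs <- r@cellSize
  col <- floor((xy[, 1] - r@origin[1]) / cs) + 1
  rowFromBottom <- floor((xy[, 2] - r@origin[2]) / cs) + 1
  row <- d[1] - rowFromBottom + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  # points exactly on the outer max edge are clamped into the grid
  onTop <- !is.na(xy[, 2]) & xy[, 2] == r@origin[2] + d[1] * cs
  onRight <- !is.na(xy[, 1]) & xy[, 1] == r@origin[1] + d[2] * cs
  row[onTop] <- 1L; col[onRight] <- d[2]
  bad <- bad & !(onTop | onRight)
  out <- cbind(row = as.integer(row), col = as.integer(col))
  out[bad, ] <- NA_integer_
  out
}

#' @rdname cellFromXY
#' @param cells two-column matrix of (row, col) indices.
#' @export
xyFromCell <- function(r, cells) {
  cells <- matrix(as.integer(cells), ncol = 2)
  d <- dim(r@values); cs <- r@cellSize
  x <- r@origin[1] + (cells[, 2] - 0.5) * cs
  y <- r@origin[2] + (d[1] - cells[, 1] + 0.5) * cs
  cbind(x = x, y = y)
}

#' Slope magnitude from a DEM by finite differences
#'
#' Central differences in the grid interior, one-sided differences on the
#' border; slope is the isotropic gradient magnitude
#' \eqn{\sqrt{(dz/dx)^2 + (dz/dy)^2}} (dimensionless rise/run).
#'
#' @param dem a \linkS4class{GridRaster} of elevations in metres.
#' @return A \linkS4class{GridRaster} of slope.
#' @export
slopeRaster <- function(dem) {
  z <- dem@values; cs <- dem@cellSize
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2L || nc < 2L)
    stop("slope needs at least a 2 x 2 DEM")
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * cs)
  gx[, 1] <- (z[, 2] - z[, 1]) / cs
  gx[, nc] <- (z[, nc] - z[, nc - 1]) / cs
  # row index grows southward, so dz/dy flips sign; magnitude is unaffected
  gy[2:(nr - 1), ] <- (z[1:(nr - 2), ] - z[3:nr, ]) / (2 * cs)
  gy[1, ] <- (z[1, ] - z[2, ]) / cs
  gy[nr, ] <- (z[nr - 1, ] - z[nr, ]) / cs
  gridRaster(sqrt(gx^2 + gy^2), cs, dem@origin)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows north to
#' south. Non-finite cells are written as the nodata value.
#'
#' @param r a \linkS4class{GridRaster}.
#' @param path file path (conventionally \code{.asc}).
#' @param nodata value standing for missing/unreachable cells on disk.
#' @return \code{readAsciiGrid} returns a \linkS4class{GridRaster}; nodata
#'   cells come back as \code{NA}.
#' @export
writeAsciiGrid <- function(r, path, nodata = -9999) {
  d <- dim(r@values)
  v <- r@values
  v[!is.finite(v)] <- nodata
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", r@origin[1]),
           sprintf("yllcorner %.10g", r@origin[2]),
           sprintf("cellsize %.10g", r@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(apply(v, 1, function(row) paste(format(row, trim = TRUE,
    scientific = FALSE, digits = 15), collapse = " ")), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(body) == nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(vals["nodata_value"])) m[m == vals["nodata_value"]] <- NA
  gridRaster(m, unname(vals["cellsize"]),
             unname(c(vals["xllcorner"], vals["yllcorner"])))
}
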