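#' Read and validate the long service-record table
#'
#' Expects CSV columns \code{facility_id, year, indicator, count}. Rows with
#' duplicate (facility, year, indicator) keys are summed; unknown indicators
#' are rejected; years outside the study window are dropped with a message.
#'
#' @param path CSV path, or a \code{data.frame} already in memory.
#' @param years study window kept (default 2016-2022).
#' @return validated, aggregated \code{data.frame}.
#' @examples
#' df <- data.frame(facility_id = "f1", year = 2016,
#'                  indicator = "malaria", count = c(3, 2))
#' readServiceRecords(df)
#' @export
readServiceRecords <- function(path, years = STUDY_YEARS) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("facility_id", "year", "indicator", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("service records missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    df <- df[, need]
    df$year <- as.integer(df$year); df$count <- as.integer(df$count)
    return(df)
  }
  df$year <- as.integer(df$year)
  df$count <- suppressWarnings(as.numeric(df$count))
  if (anyNA(df$count))
    stop("non-numeric count at row(s): ",
         paste(utils::head(which(is.na(df$count)), 5), collapse = ", "))
  neg <- which(df$count < 0)
  if (length(neg))
    stop("negative count at row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  unknown <- setdiff(unique(df$indicator), SERVICE_INDICATORS)
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "))
  out <- df$year < min(years) | df$year > max(years)
  if (any(out)) {
    message(sum(out), " record(s) outside ", min(years), "-", max(years),
            " dropped")
    df <- df[!out, , drop = FALSE]
  }
  agg <- stats::aggregate(count ~ facility_id + year + indicator, df, sum)
  agg <- agg[order(agg$facility_id, agg$year, agg$indicator), need]
  rownames(agg) <- NULL
  agg
}

#' Read and validate the facility registry
#'
#' Expects CSV columns \code{facility_id, name, type, ownership, district_id,
#' x, y}; enforces unique ids and the type/ownership enumerations.
#'
#' @param path CSV path or \code{data.frame}.
#' @return validated registry \code{data.frame}.
#' @export
readFacilityRegistry <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("facility_id", "name", "type", "ownership", "district_id", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("registry missing column(s): ", paste(missing, collapse = ", "))
  dup <- df$facility_id[duplicated(df$facility_id)]
  if (length(dup))
    stop("duplicate facility_id: ", paste(unique(dup), collapse = ", "))
  badType <- setdiff(unique(df$type), FACILITY_TYPES)
  if (length(badType))
    stop("unknown facility type(s): ", paste(badType, collapse = ", "),
         " (expected ", paste(FACILITY_TYPES, collapse = ", "), ")")
  badOwn <- setdiff(unique(df$ownership), OWNERSHIP_LEVELS)
  if (length(badOwn))
    stop("unknown ownership value(s): ", paste(badOwn, collapse = ", "))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  rownames(df) <- NULL
  df[, need]
}

#' Read district polygons from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of Polygon features carrying a
#'   \code{district_id} property, or an already-built named list of rings.
#' @return named list of closed polygon rings.
#' @export
readDistricts <- function(path) {
  if (is.list(path) && !is.null(names(path))) return(path)
  feats <- readGeoJSON(path)
  rings <- lapply(feats, `[[`, "coords")
  ids <- vapply(feats, function(f) as.character(f$properties$district_id), "")
  if (anyNA(ids) || any(ids == ""))
    stop("district features must carry a district_id property")
  stats::setNames(rings, ids)
}

# candidate repairs for a decimal-shift corruption: each ordinate scaled by
# 10 or 1/10, singly first, then jointly
.decimalCandidates <- function(pt) {
  list(c(pt[1] * 10, pt[2]), c(pt[1] / 10, pt[2]),
       c(pt[1], pt[2] * 10), c(pt[1], pt[2] / 10),
       c(pt[1] * 10, pt[2] * 10), c(pt[1] / 10, pt[2] / 10),
       c(pt[1] * 10, pt[2] / 10), c(pt[1] / 10, pt[2] * 10))
}

# the repair cascade on an out-of-district point: ordinate swap first, then
# decimal shifts, first candidate inside the district wins; NULL if none hits
.repairFirstHit <- function(ring, pt) {
  swapped <- rev(pt)
  if (pointInPolygon(ring, rbind(swapped)))
    return(list(status = "repaired_swap", pt = swapped))
  for (cand in .decimalCandidates(pt))
    if (pointInPolygon(ring, rbind(cand)))
      return(list(status = "repaired_decimal", pt = cand))
  NULL
}

#' Check and repair facility locations against district boundaries
#'
#' Spatially joins each facility's published coordinates with its assigned
#' district. Non-matching points are repaired in a fixed candidate order:
#' (1) ordinate swap; (2) decimal shifts (single ordinate first, then joint);
#' the first candidate falling inside the district wins. Points within
#' \code{tolerance} metres of the district boundary are treated as boundary
#' inaccuracies and left unchanged (\code{boundary_tolerated}); anything else
#' is \code{unresolved} and is excluded from travel-time sourcing while
#' remaining available to temporal/classification analyses. An optional
#' gazetteer of reference place locations widens the boundary-tolerance rule:
#' a facility co-located with a gazetteer place (same \code{name}, within
#' \code{tolerance}) is also tolerated unchanged.
#'
#' @param registry validated registry \code{data.frame}.
#' @param districts named list of polygon rings (or GeoJSON path).
#' @param tolerance metres; default 2000.
#' @param gazetteer optional \code{data.frame} with \code{name, x, y}.
#' @return list with \code{qa} (one row per facility: status, original and
#'   final coordinates) and \code{registry} (corrected coordinates).
#' @export
qaLocations <- function(registry, districts, tolerance = 2000,
                        gazetteer = NULL) {
  districts <- readDistricts(districts)
  unknown <- setdiff(unique(registry$district_id), names(districts))
  if (length(unknown))
    stop("district_id not present in district polygons: ",
         paste(unknown, collapse = ", "))
  n <- nrow(registry)
  status <- character(n)
  fx <- registry$x; fy <- registry$y
  for (i in seq_len(n)) {
    ring <- districts[[registry$district_id[i]]]
    pt <- c(registry$x[i], registry$y[i])
    if (pointInPolygon(ring, rbind(pt))) {
      status[i] <- "ok"
      next
    }
    hit <- .repairFirstHit(ring, pt)
    if (!is.null(hit)) {
      status[i] <- hit$status
      fx[i] <- hit$pt[1]; fy[i] <- hit$pt[2]
      next
    }
    tolerated <- distanceToBoundary(ring, rbind(pt)) <= tolerance
    if (!tolerated && !is.null(gazetteer)) {
      m <- gazetteer[gazetteer$name == registry$name[i], , drop = FALSE]
      if (nrow(m))
        tolerated <- any(sqrt((m$x - pt[1])^2 + (m$y - pt[2])^2) <= tolerance)
    }
    status[i] <- if (tolerated) "boundary_tolerated" else "unresolved"
  }
  if (any(status == "unresolved"))
    warning(sum(status == "unresolved"),
            " facility location(s) unresolved; excluded from travel-time sourcing")
  qa <- data.frame(facility_id = registry$facility_id, status = status,
                   original_x = registry$x, original_y = registry$y,
                   final_x = fx, final_y = fy, stringsAsFactors = FALSE)
  corrected <- registry
  corrected$x <- fx; corrected$y <- fy
  list(qa = qa, registry = corrected)
}
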