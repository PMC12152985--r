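#' Land-cover legend used by the synthetic generator and friction defaults
#' @export
LANDCOVER_CLASSES <- c(grassland = 1, cropland = 2, dense_vegetation = 3,
                       builtup = 4)

# independent, reproducible RNG streams per generator stage
.subSeeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8L)
  names(s) <- c("terrain", "water", "roads", "population", "districts",
                "facilities", "histories", "corruption")
  s
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Configure a synthetic study region
#'
#' Builds a validated \linkS4class{RegionScenario}. Defaults describe the
#' study conditions the package is exercised under: a 20 x 20 km region at
#' 100 m resolution with 150 facilities whose type composition, type-conditional
#' ownership and functional-archetype mix follow the published 2022 regional
#' facility census (71.0\% CHPS, 20.9\% health centres, 6.1\% hospitals, 2.0\%
#' maternity homes; 85\% government overall; 20.9\% newly operational, 3.2\%
#' no-service, and unchanged + increased together 60.6\%).
#'
#' @param nRows,nCols grid size in cells.
#' @param cellSize cell edge, metres.
#' @param seed integer seed; all layers are deterministic in it.
#' @param nFacilities number of facilities.
#' @param typeMix,ownershipMix,archetypeMix probability vectors (ownershipMix
#'   may be a type x ownership matrix of conditional probabilities).
#' @param coordErrorRate fraction of facilities whose published coordinates
#'   are corrupted (ordinate swap or decimal shift).
#' @param totalPopulation persons in the baseline (2021) raster.
#' @param growthRatePct annual population growth, percent.
#' @param subgroupProps named fractions for \code{wocba} and \code{under5}.
#' @param nDistricts number of rectangular districts.
#' @param waterEnabled generate a river barrier.
#' @return A \linkS4class{RegionScenario}.
#' @examples
#' sc <- regionScenario(nRows = 40, nCols = 40, nFacilities = 20, seed = 7)
#' @export
regionScenario <- function(nRows = 200L, nCols = 200L, cellSize = 100,
    seed = 1L, nFacilities = 150L,
    typeMix = c(CHPS = 397, HealthCentre = 117, Hospital = 34,
                MaternityHome = 11) / 559,
    ownershipMix = NULL,
    archetypeMix = c(closed = 0.020, newly_operational = 0.209,
                     no_service = 0.032, oscillating = 0.016,
                     existing_unchanged = 0.350, existing_increased = 0.256,
                     existing_decreased = 0.060, existing_varying = 0.057),
    coordErrorRate = 0.05, totalPopulation = 70000, growthRatePct = 2,
    subgroupProps = c(wocba = 0.24, under5 = 0.13),
    nDistricts = 6L, waterEnabled = TRUE) {
  if (is.null(ownershipMix)) {
    # type-conditional ownership of the 2022 facility census
    ownershipMix <- rbind(
      CHPS          = c(344, 3, 50) / 397,
      HealthCentre  = c(117, 0, 0) / 117,
      Hospital      = c(14, 5, 15) / 34,
      MaternityHome = c(0, 0, 11) / 11)
    colnames(ownershipMix) <- OWNERSHIP_LEVELS
  }
  new("RegionScenario", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSize = cellSize, seed = as.integer(seed),
      nFacilities = as.integer(nFacilities), typeMix = typeMix,
      ownershipMix = ownershipMix, archetypeMix = archetypeMix,
      coordErrorRate = coordErrorRate, totalPopulation = totalPopulation,
      growthRatePct = growthRatePct, subgroupProps = subgroupProps,
      nDistricts = as.integer(nDistricts), waterEnabled = waterEnabled)
}

setMethod("show", "RegionScenario", function(object) {
  cat(sprintf("RegionScenario: %d x %d cells @ %g m, seed %d\n",
              object@nRows, object@nCols, object@cellSize, object@seed))
  cat(sprintf("  %d facilities, %d districts, population %g (r = %g%%/yr)\n",
              object@nFacilities, object@nDistricts, object@totalPopulation,
              object@growthRatePct))
  invisible(object)
})

# smooth random field: sum of random-phase sinusoids over the unit square
.smoothField <- function(nr, nc, nWaves = 8, maxFreq = 4) {
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  z <- matrix(0, nr, nc)
  for (k in seq_len(nWaves)) {
    fx <- stats::runif(1, 0.5, maxFreq) * sample(c(-1, 1), 1)
    fy <- stats::runif(1, 0.5, maxFreq) * sample(c(-1, 1), 1)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    z <- z + amp * sin(2 * pi * (outer(ys, xs, function(y, x) fx * x + fy * y)) + ph)
  }
  z
}

#' Generate terrain layers: DEM, land cover and water
#'
#' The DEM is a smooth random field rescaled to 50-400 m elevation; land cover
#' is drawn from the four-class legend by thresholding independent smooth
#' fields; water (when enabled) is a river polyline wandering from the north
#' to the south edge, forming a connected travel barrier once rasterised.
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @return list with \code{dem} and \code{landcover}
#'   (\linkS4class{GridRaster}s) and \code{water} (list of polyline features,
#'   empty when water is disabled).
#' @export
generateTerrain <- function(scenario) {
  stopifnot(is(scenario, "RegionScenario"))
  validObject(scenario)
  seeds <- .subSeeds(scenario@seed)
  nr <- scenario@nRows; nc <- scenario@nCols; cs <- scenario@cellSize
  dem <- .withSeed(seeds[["terrain"]], {
    z <- .smoothField(nr, nc)
    50 + 350 * (z - min(z)) / (max(z) - min(z))
  })
  landcover <- .withSeed(seeds[["terrain"]] + 1L, {
    u <- .smoothField(nr, nc)
    v <- .smoothField(nr, nc, nWaves = 6, maxFreq = 6)
    lc <- matrix(LANDCOVER_CLASSES[["grassland"]], nr, nc)
    lc[u > stats::quantile(u, 0.55)] <- LANDCOVER_CLASSES[["cropland"]]
    lc[u > stats::quantile(u, 0.80)] <- LANDCOVER_CLASSES[["dense_vegetation"]]
    lc[v > stats::quantile(v, 0.95)] <- LANDCOVER_CLASSES[["builtup"]]
    lc
  })
  water <- if (scenario@waterEnabled) {
    .withSeed(seeds[["water"]], {
      w <- nc * cs; h <- nr * cs
      n <- max(10L, nr %/% 8L)
      ys <- seq(h, 0, length.out = n)
      xs <- numeric(n)
      xs[1] <- stats::runif(1, 0.25 * w, 0.75 * w)
      for (i in 2:n)
        xs[i] <- min(max(xs[i - 1] + stats::rnorm(1, 0, 0.04 * w), 0.05 * w),
                     0.95 * w)
      list(list(type = "LineString", coords = cbind(x = xs, y = ys),
                properties = list(kind = "river")))
    })
  } else list()
  list(dem = gridRaster(dem, cs), landcover = gridRaster(landcover, cs),
       water = water)
}

#' Generate the synthetic road network
#'
#' A primary road crossing the full west-east extent, a secondary road
#' crossing north-south (intersecting the primary), and tertiary branches
#' rooted on existing roads: the network is connected and touches at least two
#' region edges. Each feature carries a \code{speed_class} property.
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @return list of polyline features with \code{speed_class} in
#'   \code{c("primary", "secondary", "tertiary")}.
#' @export
generateRoads <- function(scenario) {
  stopifnot(is(scenario, "RegionScenario"))
  seeds <- .subSeeds(scenario@seed)
  .withSeed(seeds[["roads"]], {
    w <- scenario@nCols * scenario@cellSize
    h <- scenario@nRows * scenario@cellSize
    wiggle <- function(from, to, n, spread) {
      # polyline from 'from' to 'to' with lateral random-walk wiggle
      t <- seq(0, 1, length.out = n)
      base <- cbind(from[1] + t * (to[1] - from[1]),
                    from[2] + t * (to[2] - from[2]))
      perp <- c(-(to[2] - from[2]), to[1] - from[1])
      perp <- perp / sqrt(sum(perp^2))
      off <- cumsum(stats::rnorm(n, 0, spread)); off <- off - t * off[n]
      off[1] <- 0
      pts <- base + outer(off, perp)
      pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), h)
      colnames(pts) <- c("x", "y"); pts
    }
    primary <- wiggle(c(0, stats::runif(1, 0.3, 0.7) * h),
                      c(w, stats::runif(1, 0.3, 0.7) * h), 15, 0.02 * h)
    secondary <- wiggle(c(stats::runif(1, 0.3, 0.7) * w, h),
                        c(stats::runif(1, 0.3, 0.7) * w, 0), 13, 0.02 * w)
    feats <- list(
      list(type = "LineString", coords = primary,
           properties = list(speed_class = "primary")),
      list(type = "LineString", coords = secondary,
           properties = list(speed_class = "secondary")))
    nBranch <- 6L
    for (b in seq_len(nBranch)) {
      host <- feats[[sample.int(length(feats), 1)]]$coords
      v <- host[sample.int(nrow(host), 1), ]
      target <- c(stats::runif(1, 0.1 * w, 0.9 * w),
                  stats::runif(1, 0.1 * h, 0.9 * h))
      feats[[length(feats) + 1L]] <- list(type = "LineString",
        coords = wiggle(v, target, 8, 0.015 * h),
        properties = list(speed_class = "tertiary"))
    }
    feats
  })
}

#' Generate the baseline gridded population
#'
#' Population mass is concentrated in a handful of Gaussian settlement
#' clusters over a small uniform rural floor, then rescaled so the raster sums
#' exactly to the configured regional total (spatially clustered by
#' construction).
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @return A \linkS4class{GridRaster} of persons per cell.
#' @export
generatePopulation <- function(scenario) {
  stopifnot(is(scenario, "RegionScenario"))
  stopifnot(scenario@totalPopulation > 0)
  seeds <- .subSeeds(scenario@seed)
  .withSeed(seeds[["population"]], {
    nr <- scenario@nRows; nc <- scenario@nCols
    k <- 5L
    cr <- stats::runif(k, 0.1, 0.9) * nr
    cc <- stats::runif(k, 0.1, 0.9) * nc
    sd <- stats::runif(k, 0.02, 0.08) * max(nr, nc)
    wgt <- stats::rgamma(k, 2, 1)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dens <- matrix(0.02, nr, nc)
    for (i in seq_len(k))
      dens <- dens + wgt[i] * exp(-((rows - cr[i])^2 + (cols - cc[i])^2) /
                                    (2 * sd[i]^2))
    dens <- dens * scenario@totalPopulation / sum(dens)
    gridRaster(dens, scenario@cellSize)
  })
}

#' Generate rectangular districts partitioning the region
#'
#' Recursive axis-aligned splits of the region rectangle at seeded fractions;
#' the resulting rectangles exactly partition the region.
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @return named list of closed polygon rings (\code{D01}, \code{D02}, ...).
#' @export
generateDistricts <- function(scenario) {
  stopifnot(is(scenario, "RegionScenario"))
  seeds <- .subSeeds(scenario@seed)
  .withSeed(seeds[["districts"]], {
    w <- scenario@nCols * scenario@cellSize
    h <- scenario@nRows * scenario@cellSize
    rects <- list(c(0, 0, w, h))  # xmin, ymin, xmax, ymax
    while (length(rects) < scenario@nDistricts) {
      areas <- vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0)
      i <- which.max(areas)
      r <- rects[[i]]
      f <- stats::runif(1, 0.35, 0.65)
      if ((r[3] - r[1]) >= (r[4] - r[2])) {
        xm <- r[1] + f * (r[3] - r[1])
        halves <- list(c(r[1], r[2], xm, r[4]), c(xm, r[2], r[3], r[4]))
      } else {
        ym <- r[2] + f * (r[4] - r[2])
        halves <- list(c(r[1], r[2], r[3], ym), c(r[1], ym, r[3], r[4]))
      }
      rects <- c(rects[-i], halves)
    }
    rings <- lapply(rects, function(r)
      cbind(x = c(r[1], r[3], r[3], r[1], r[1]),
            y = c(r[2], r[2], r[4], r[4], r[2])))
    names(rings) <- sprintf("D%02d", seq_along(rings))
    rings
  })
}

#' Generate the facility registry with injected coordinate errors
#'
#' Facilities are placed with probability proportional to population (plus a
#' rural floor), assigned a type from \code{typeMix} and an ownership from the
#' (optionally type-conditional) \code{ownershipMix}, and attributed to the
#' district containing their true location. A \code{coordErrorRate} fraction
#' get corrupted published coordinates: an ordinate swap or a decimal shift
#' (one ordinate multiplied or divided by 10). A corruption that would leave
#' the point inside its own district is undetectable by a spatial join, so the
#' generator falls back to a decimal shift (and records the kind actually
#' applied) to keep every injected error recoverable in principle.
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @param districts named list of polygon rings partitioning the region.
#' @param population optional \linkS4class{GridRaster} weighting placement.
#' @return list with \code{registry} (published coordinates) and
#'   \code{groundTruth} (true coordinates and injected error kind).
#' @export
generateFacilities <- function(scenario, districts, population = NULL) {
  stopifnot(is(scenario, "RegionScenario"))
  if (length(districts) == 0L) stop("district set must not be empty")
  seeds <- .subSeeds(scenario@seed)
  n <- scenario@nFacilities
  nr <- scenario@nRows; nc <- scenario@nCols; cs <- scenario@cellSize
  template <- gridRaster(matrix(0, nr, nc), cs)
  placement <- .withSeed(seeds[["facilities"]], {
    wts <- if (is.null(population)) rep(1, nr * nc) else
      as.numeric(population@values) + max(population@values) * 0.01
    cellIdx <- sample.int(nr * nc, n, replace = TRUE, prob = wts)
    row <- (cellIdx - 1L) %% nr + 1L
    col <- (cellIdx - 1L) %/% nr + 1L
    ctr <- xyFromCell(template, cbind(row, col))
    x <- ctr[, 1] + stats::runif(n, -0.4, 0.4) * cs
    y <- ctr[, 2] + stats::runif(n, -0.4, 0.4) * cs
    type <- sample(names(scenario@typeMix), n, replace = TRUE,
                   prob = scenario@typeMix)
    om <- scenario@ownershipMix
    ownership <- if (is.matrix(om)) {
      vapply(type, function(tp) sample(colnames(om), 1, prob = om[tp, ]), "")
    } else sample(names(om), n, replace = TRUE, prob = om)
    list(x = x, y = y, type = type, ownership = unname(ownership))
  })
  districtId <- rep(NA_character_, n)
  for (d in names(districts)) {
    hit <- pointInPolygon(districts[[d]], cbind(placement$x, placement$y))
    districtId[hit & is.na(districtId)] <- d
  }
  if (anyNA(districtId)) {
    # points exactly on a shared district edge: snap to the nearest district
    for (i in which(is.na(districtId))) {
      dist <- vapply(districts, function(rg)
        distanceToBoundary(rg, cbind(placement$x[i], placement$y[i])), 0)
      districtId[i] <- names(districts)[which.min(dist)]
    }
  }
  ids <- sprintf("F%04d", seq_len(n))
  registry <- data.frame(
    facility_id = ids,
    name = paste0(placement$type, "_", ids),
    type = placement$type, ownership = placement$ownership,
    district_id = districtId, x = placement$x, y = placement$y,
    stringsAsFactors = FALSE)
  nBad <- round(scenario@coordErrorRate * n)
  errKind <- rep("none", n)
  pub <- cbind(placement$x, placement$y)
  .withSeed(seeds[["corruption"]], {
    bad <- if (nBad > 0) sample.int(n, nBad) else integer()
    for (i in bad) {
      ring <- districts[[districtId[i]]]
      truePt <- c(placement$x[i], placement$y[i])
      wantSwap <- stats::runif(1) < 0.5
      decVariants <- list(c(truePt[1] * 10, truePt[2]),
                          c(truePt[1] / 10, truePt[2]),
                          c(truePt[1], truePt[2] * 10),
                          c(truePt[1], truePt[2] / 10))
      decVariants <- decVariants[sample.int(4)]
      variants <- c(list(list(pt = rev(truePt), kind = "swapped")),
                    lapply(decVariants,
                           function(p) list(pt = p, kind = "decimal_shift")))
      if (!wantSwap) variants <- c(variants[-1], variants[1])
      # a usable corruption must leave the district (else the spatial join
      # cannot see it) and the repair cascade must round-trip to the truth
      # (else the first in-district candidate would "repair" it wrongly)
      for (v in variants) {
        if (pointInPolygon(ring, rbind(v$pt))) next
        rep <- .repairFirstHit(ring, v$pt)
        if (is.null(rep)) next
        if (isTRUE(all.equal(rep$pt, truePt, tolerance = 1e-9))) {
          pub[i, ] <- v$pt
          errKind[i] <- v$kind
          break
        }
      }
    }
  })
  registry$x <- pub[, 1]; registry$y <- pub[, 2]
  groundTruth <- data.frame(
    facility_id = ids, coord_error = errKind,
    true_x = placement$x, true_y = placement$y, stringsAsFactors = FALSE)
  list(registry = registry, groundTruth = groundTruth)
}

# onboarding ladder per facility type; caesarean is hospital-only
.serviceLadder <- function(type) {
  switch(type,
    Hospital = c("pentavalent1", "outpatient", "malaria", "antenatal",
                 "birth", "caesarean"),
    MaternityHome = c("antenatal", "birth", "outpatient"),
    c("pentavalent1", "outpatient", "malaria", "antenatal", "birth"))
}

.sample1 <- function(x) x[sample.int(length(x), 1L)]

.archetypePattern <- function(archetype, ladder, years = STUDY_YEARS) {
  nY <- length(years)
  maxL <- length(ladder)
  m <- matrix(FALSE, nY, maxL, dimnames = list(years, ladder))
  setRow <- function(y, L) if (L > 0) m[as.character(y), seq_len(L)] <<- TRUE
  switch(archetype,
    no_service = NULL,
    closed = {
      L <- sample.int(maxL, 1)
      last <- sample(years[-nY][-1], 1)  # closes somewhere in 2017..2021
      for (y in years[years <= last]) setRow(y, L)
    },
    newly_operational = {
      s <- sample(years[-1], 1)
      L <- sample.int(maxL, 1)
      for (y in years[years >= s]) setRow(y, min(L, 1 + (y - s)))
    },
    oscillating = {
      mid <- years[-c(1, nY)]
      on <- mid[stats::runif(length(mid)) < 0.5]
      if (!length(on)) on <- sample(mid, 1)
      L <- sample.int(maxL, 1)
      for (y in on) setRow(y, L)
    },
    existing_unchanged = {
      L <- sample.int(maxL, 1)
      for (y in years) setRow(y, L)
    },
    existing_increased = {
      L16 <- sample.int(maxL - 1L, 1)
      L22 <- .sample1(seq(L16 + 1L, maxL))
      Ls <- round(seq(L16, L22, length.out = nY))
      for (i in seq_len(nY)) setRow(years[i], Ls[i])
    },
    existing_decreased = {
      L22 <- sample.int(maxL - 1L, 1)
      L16 <- .sample1(seq(L22 + 1L, maxL))
      Ls <- round(seq(L16, L22, length.out = nY))
      for (i in seq_len(nY)) setRow(years[i], Ls[i])
    },
    existing_varying = {
      L <- sample.int(maxL, 1)
      bump <- sample(years[-c(1, nY)], 1)
      for (y in years) setRow(y, L)
      Lb <- if (L < maxL) L + 1L else L - 1L
      m[as.character(bump), ] <- FALSE
      setRow(bump, Lb)
    },
    stop("unknown archetype: ", archetype))
  m
}

# zero-truncated Poisson by inverse CDF
.rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Generate seven-year service histories per facility
#'
#' Each facility is assigned a functional archetype from the scenario's
#' \code{archetypeMix}; its yearly presence/absence pattern over the six
#' indicators follows the archetype exactly (so a noise-free classifier
#' recovers every label), with services onboarded along a type-specific ladder
#' (immunisation first, then outpatient/malaria, then antenatal, then birth
#' care, caesarean only in hospitals). Counts for provided services are
#' zero-truncated Poisson with a type-dependent mean.
#'
#' @param registry facility registry \code{data.frame}.
#' @param scenario a \linkS4class{RegionScenario}.
#' @param countMeans named Poisson means per facility type.
#' @return list with \code{records} (long facility/year/indicator/count table,
#'   positive counts only) and \code{groundTruth} (facility_id, archetype).
#' @export
generateServiceHistories <- function(registry, scenario,
    countMeans = c(CHPS = 120, HealthCentre = 600, Hospital = 3000,
                   MaternityHome = 80)) {
  stopifnot(nrow(registry) > 0)
  badArch <- setdiff(names(scenario@archetypeMix),
                     setdiff(FUNCTIONAL_CLASSES, "other_intermittent"))
  if (length(badArch)) stop("unknown archetype: ", paste(badArch, collapse = ", "))
  seeds <- .subSeeds(scenario@seed)
  .withSeed(seeds[["histories"]], {
    n <- nrow(registry)
    # the archetype mix defines the region's composition, not a sampling
    # distribution: allocate counts by largest remainder, then permute
    mix <- scenario@archetypeMix
    base <- floor(mix * n)
    rest <- n - sum(base)
    if (rest > 0) {
      frac <- mix * n - base
      base[order(frac, decreasing = TRUE)[seq_len(rest)]] <-
        base[order(frac, decreasing = TRUE)[seq_len(rest)]] + 1
    }
    archetype <- sample(rep(names(mix), base))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ladder <- .serviceLadder(registry$type[i])
      pat <- .archetypePattern(archetype[i], ladder)
      idx <- which(pat, arr.ind = TRUE)
      if (nrow(idx)) {
        lambda <- countMeans[[registry$type[i]]]
        rows[[i]] <- data.frame(
          facility_id = registry$facility_id[i],
          year = STUDY_YEARS[idx[, 1]],
          indicator = ladder[idx[, 2]],
          count = .rztpois(nrow(idx), lambda),
          stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(records))
      records <- data.frame(facility_id = character(), year = integer(),
                            indicator = character(), count = integer())
    rownames(records) <- NULL
    list(records = records,
         groundTruth = data.frame(facility_id = registry$facility_id,
                                  archetype = archetype,
                                  stringsAsFactors = FALSE))
  })
}

#' Generate a complete synthetic region
#'
#' Runs every layer generator under the scenario's seed and bundles the result
#' with merged ground truth.
#'
#' @param scenario a \linkS4class{RegionScenario}.
#' @return A \linkS4class{SyntheticRegion}.
#' @examples
#' reg <- generateRegion(regionScenario(nRows = 40, nCols = 40,
#'                                      nFacilities = 25, seed = 11))
#' head(syntheticRegistry(reg))
#' @export
generateRegion <- function(scenario) {
  validObject(scenario)
  terr <- generateTerrain(scenario)
  roads <- generateRoads(scenario)
  pop <- generatePopulation(scenario)
  districts <- generateDistricts(scenario)
  fac <- generateFacilities(scenario, districts, pop)
  hist <- generateServiceHistories(fac$registry, scenario)
  gt <- merge(fac$groundTruth, hist$groundTruth, by = "facility_id")
  gt <- gt[order(gt$facility_id), ]
  rownames(gt) <- NULL
  new("SyntheticRegion", scenario = scenario, dem = terr$dem,
      landcover = terr$landcover, population = pop, roads = roads,
      water = terr$water, districts = districts, registry = fac$registry,
      records = hist$records, groundTruth = gt)
}

#' Accessors for SyntheticRegion components
#' @param region a \linkS4class{SyntheticRegion}.
#' @export
syntheticRegistry <- function(region) region@registry

#' @rdname syntheticRegistry
#' @export
syntheticRecords <- function(region) region@records

#' @rdname syntheticRegistry
#' @export
syntheticGroundTruth <- function(region) region@groundTruth

setMethod("show", "SyntheticRegion", function(object) {
  cat(sprintf("SyntheticRegion: %d x %d cells, %d facilities, %d districts\n",
              object@scenario@nRows, object@scenario@nCols,
              nrow(object@registry), length(object@districts)))
  cat(sprintf("  %d service records over %d-%d; %d corrupted coordinates\n",
              nrow(object@records), min(STUDY_YEARS), max(STUDY_YEARS),
              sum(object@groundTruth$coord_error != "none")))
  invisible(object)
})

#' Write all layers of a synthetic region to disk
#'
#' Registry, service records and ground truth as CSV; DEM, land cover and
#' population as ASCII grids; roads, water and districts as GeoJSON; the
#' scenario as YAML.
#'
#' @param region a \linkS4class{SyntheticRegion}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
writeRegion <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(region@registry, p("registry.csv"), row.names = FALSE)
  utils::write.csv(region@records, p("service_records.csv"), row.names = FALSE)
  utils::write.csv(region@groundTruth, p("ground_truth.csv"), row.names = FALSE)
  writeAsciiGrid(region@dem, p("dem.asc"))
  writeAsciiGrid(region@landcover, p("landcover.asc"))
  writeAsciiGrid(region@population, p("population.asc"))
  writeGeoJSON(region@roads, p("roads.geojson"))
  if (length(region@water)) writeGeoJSON(region@water, p("water.geojson"))
  distFeat <- lapply(names(region@districts), function(d)
    list(type = "Polygon", coords = region@districts[[d]],
         properties = list(district_id = d)))
  writeGeoJSON(distFeat, p("districts.geojson"))
  sc <- region@scenario
  yaml::write_yaml(list(
    nRows = sc@nRows, nCols = sc@nCols, cellSize = sc@cellSize,
    seed = sc@seed, nFacilities = sc@nFacilities,
    typeMix = as.list(sc@typeMix),
    archetypeMix = as.list(sc@archetypeMix),
    coordErrorRate = sc@coordErrorRate,
    totalPopulation = sc@totalPopulation,
    growthRatePct = sc@growthRatePct,
    subgroupProps = as.list(sc@subgroupProps),
    nDistricts = sc@nDistricts, waterEnabled = sc@waterEnabled),
    p("scenario.yaml"))
  out <- c("registry.csv", "service_records.csv", "ground_truth.csv",
           "dem.asc", "landcover.asc", "population.asc", "roads.geojson",
           "districts.geojson", "scenario.yaml")
  invisible(stats::setNames(file.path(dir, out), out))
}
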