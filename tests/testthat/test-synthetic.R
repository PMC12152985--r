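test_that("scenario validation rejects bad configurations", {
  expect_error(regionScenario(nRows = 5), "at least 10")
  expect_error(regionScenario(typeMix = c(CHPS = 0.5, HealthCentre = 0.2,
                                          Hospital = 0.2,
                                          MaternityHome = 0.2)),
               "summing to 1")
  expect_error(regionScenario(coordErrorRate = 1.5), "\\[0, 1\\]")
})

test_that("all generators are bit-identical under a fixed seed", {
  sc <- smallScenario(seed = 9)
  a <- generateRegion(sc)
  b <- generateRegion(sc)
  expect_identical(gridValues(a@dem), gridValues(b@dem))
  expect_identical(gridValues(a@landcover), gridValues(b@landcover))
  expect_identical(gridValues(a@population), gridValues(b@population))
  expect_identical(a@registry, b@registry)
  expect_identical(a@records, b@records)
  expect_identical(a@groundTruth, b@groundTruth)
  expect_identical(lapply(a@roads, `[[`, "coords"),
                   lapply(b@roads, `[[`, "coords"))
})

test_that("water can be disabled and roads are independent of facilities", {
  scNoWater <- smallScenario(seed = 4, waterEnabled = FALSE)
  terr <- generateTerrain(scNoWater)
  expect_length(terr$water, 0)
  wmask <- rasterizeLines(terr$water, terr$dem)
  expect_equal(sum(gridValues(wmask)), 0)
  # roads do not depend on the facility layer
  r1 <- generateRoads(smallScenario(seed = 4, n = 0L))
  r2 <- generateRoads(smallScenario(seed = 4, n = 40L))
  expect_identical(lapply(r1, `[[`, "coords"), lapply(r2, `[[`, "coords"))
})

test_that("road network touches >= 2 region edges and is connected once rasterised", {
  sc <- smallScenario(seed = 6)
  roads <- generateRoads(sc)
  template <- gridRaster(matrix(0, sc@nRows, sc@nCols), sc@cellSize)
  mask <- gridValues(rasterizeLines(roads, template)) > 0
  edgeTouches <- c(any(mask[1, ]), any(mask[nrow(mask), ]),
                   any(mask[, 1]), any(mask[, ncol(mask)]))
  expect_gte(sum(edgeTouches), 2)
  # flood fill from one road cell reaches all road cells (8-connected)
  start <- which(mask, arr.ind = TRUE)[1, ]
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- list(start); seen[start[1], start[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- p[1] + dr; c2 <- p[2] + dc
      if (r2 < 1 || r2 > nrow(mask) || c2 < 1 || c2 > ncol(mask)) next
      if (mask[r2, c2] && !seen[r2, c2]) {
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1L]] <- c(r2, c2)
      }
    }
  }
  expect_true(all(seen[mask]))
})

test_that("population raster conserves the configured total and is clustered", {
  sc <- smallScenario(seed = 2)
  pop <- generatePopulation(sc)
  v <- gridValues(pop)
  expect_true(all(v >= 0))
  expect_lt(abs(sum(v) - sc@totalPopulation) / sc@totalPopulation, 1e-3)
  # clustering: variance of 10x10 block sums far exceeds a uniform shuffle
  blockVar <- function(m) {
    blocks <- sapply(seq(1, nrow(m), 10), function(r)
      sapply(seq(1, ncol(m), 10), function(c)
        sum(m[r:(r + 9), c:(c + 9)])))
    stats::var(as.numeric(blocks))
  }
  set.seed(1)
  shuffled <- matrix(sample(v), nrow(v))
  expect_gt(blockVar(v), blockVar(shuffled))
})

test_that("districts partition the region", {
  sc <- smallScenario(seed = 5)
  d <- generateDistricts(sc)
  expect_length(d, sc@nDistricts)
  template <- gridRaster(matrix(0, sc@nRows, sc@nCols), sc@cellSize)
  lab <- gridValues(rasterizePolygons(d, template))
  expect_true(all(lab >= 1))  # every cell centre claimed exactly once
})

test_that("facility generation respects mixes, district containment and error rate", {
  sc <- smallScenario(seed = 8, coordErrorRate = 0.1)
  d <- generateDistricts(sc)
  fac <- generateFacilities(sc, d)
  expect_equal(nrow(fac$registry), sc@nFacilities)
  expect_equal(sum(fac$groundTruth$coord_error != "none"),
               round(sc@coordErrorRate * sc@nFacilities))
  # true coordinates always inside the assigned district
  for (i in seq_len(nrow(fac$registry))) {
    expect_true(pointInPolygon(d[[fac$registry$district_id[i]]],
                               cbind(fac$groundTruth$true_x[i],
                                     fac$groundTruth$true_y[i])))
  }
  # zero error rate: published equals true everywhere
  fac0 <- generateFacilities(smallScenario(seed = 8, coordErrorRate = 0), d)
  expect_equal(fac0$registry$x, fac0$groundTruth$true_x)
  expect_equal(fac0$registry$y, fac0$groundTruth$true_y)
  expect_error(generateFacilities(sc, list()), "empty")
})

test_that("type frequencies converge to the configured mix at large n", {
  sc <- regionScenario(nRows = 60, nCols = 60, nFacilities = 5000L, seed = 13)
  d <- generateDistricts(sc)
  fac <- generateFacilities(sc, d)
  freq <- table(factor(fac$registry$type, FACILITY_TYPES)) / 5000
  expect_true(all(abs(freq - sc@typeMix[names(freq)]) < 0.02))
})

test_that("service histories follow the archetype definitions exactly", {
  sc <- smallScenario(seed = 10, n = 200L)
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  hist <- generateServiceHistories(reg, sc)
  cube <- provisionCube(readServiceRecords(hist$records), reg)
  op <- operationalMatrix(cube)
  gt <- hist$groundTruth
  for (i in seq_len(nrow(gt))) {
    o <- op[gt$facility_id[i], ]
    switch(gt$archetype[i],
      no_service = expect_false(any(o)),
      closed = { expect_true(o[["2016"]]); expect_false(o[["2022"]]) },
      newly_operational = { expect_false(o[["2016"]]); expect_true(o[["2022"]]) },
      oscillating = { expect_false(o[["2016"]] || o[["2022"]])
                      expect_true(any(o)) },
      expect_true(all(o)))  # every existing_* archetype is always operational
  }
  # counts are positive wherever a service is present
  expect_true(all(hist$records$count >= 1))
})

test_that("caesarean services only ever appear at hospitals", {
  sc <- smallScenario(seed = 12, n = 300L)
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  rec <- generateServiceHistories(reg, sc)$records
  caes <- rec$facility_id[rec$indicator == "caesarean"]
  types <- reg$type[match(unique(caes), reg$facility_id)]
  expect_true(all(types == "Hospital"))
})

test_that("writeRegion writes readable layers that round-trip", {
  reg <- generateRegion(smallScenario(seed = 3, nRows = 20L, nCols = 20L,
                                      n = 10L))
  dir <- withr::local_tempdir()
  writeRegion(reg, dir)
  backReg <- readFacilityRegistry(file.path(dir, "registry.csv"))
  expect_equal(backReg$facility_id, reg@registry$facility_id)
  backRec <- readServiceRecords(file.path(dir, "service_records.csv"))
  expect_equal(nrow(backRec), nrow(reg@records))
  dem <- readAsciiGrid(file.path(dir, "dem.asc"))
  expect_equal(gridValues(dem), gridValues(reg@dem), tolerance = 1e-12)
  d <- readDistricts(file.path(dir, "districts.geojson"))
  expect_equal(sort(names(d)), sort(names(reg@districts)))
})
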