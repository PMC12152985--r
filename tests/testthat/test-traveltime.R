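test_that("Tobler factor matches closed-form evaluation", {
  expect_equal(toblerFactor(0), 1)
  expect_equal(toblerFactor(-0.05), exp(0.175))
  expect_equal(toblerFactor(0.5), exp(-1.75))
  expect_equal(toblerFactor(-0.5), toblerFactor(0.4))  # symmetric about -0.05
  expect_true(all(toblerFactor(seq(-1, 1, 0.01)) <= exp(0.175)))
})

test_that("friction surface combines land cover, slope, water and roads", {
  lc <- gridRaster(matrix(LANDCOVER_CLASSES[["grassland"]], 5, 5), 100)
  flat <- gridRaster(matrix(100, 5, 5), 100)
  cfg <- speedConfig()
  fr <- buildFriction(lc, flat, cfg = cfg)
  expect_equal(gridValues(fr)[3, 3], 0.72)  # flat grassland at 5 km/h
  # water is impassable; a 40 km/h road crossing it wins (bridge)
  water <- list(list(type = "LineString",
                     coords = cbind(c(0, 500), c(250, 250)),
                     properties = list()))
  road <- list(list(type = "LineString",
                    coords = cbind(c(250, 250), c(0, 500)),
                    properties = list(speed_class = "secondary")))
  fr2 <- buildFriction(lc, flat, roads = road, water = water, cfg = cfg)
  v <- gridValues(fr2)
  expect_true(is.infinite(v[3, 1]))     # water row, off-road
  expect_equal(v[3, 3], 0.09)           # bridge cell: 3600 / 40000
  expect_equal(v[1, 3], 0.09)           # road elsewhere
  # slope moderates off-road speed
  tilted <- gridRaster(matrix(rep(seq(0, 400, 100), each = 5), 5, 5), 100)
  fr3 <- buildFriction(lc, tilted, cfg = cfg)
  expect_equal(gridValues(fr3)[3, 3], 0.72 / toblerFactor(1),
               tolerance = 1e-12)
  expect_error(buildFriction(gridRaster(matrix(99, 5, 5), 100), flat,
                             cfg = cfg), "legend")
})

test_that("travel time is zero at sources and follows the 1-D closed form", {
  row <- gridRaster(matrix(0.72, 1, 12), 100)
  tt <- cumulativeTravelTime(row, xyFromCell(row, cbind(1, 1)))
  # 100 m x 0.72 s/m = 72 s = 1.2 min per step
  expect_equal(gridValues(tt)[1, ], (0:11) * 1.2)
  expect_s4_class(tt, "TravelTimeSurface")
})

test_that("engine equals the igraph shortest-path oracle on random grids", {
  maxDelta <- 0
  for (seed in 1:10) {
    case <- randomFrictionCase(seed)
    tt <- cumulativeTravelTime(case$raster,
                               xyFromCell(case$raster, case$src),
                               snapRadius = 0)
    want <- igraphTravelTime(case$cost, 100, case$src)
    d <- abs(gridValues(tt) - want)
    d[is.infinite(gridValues(tt)) & is.infinite(want)] <- 0
    maxDelta <- max(maxDelta, max(d))
  }
  expect_lt(maxDelta, 1e-9)
})

test_that("adding a source never increases travel time anywhere", {
  for (seed in 11:15) {
    case <- randomFrictionCase(seed, nSrc = 1)
    t1 <- gridValues(cumulativeTravelTime(case$raster,
                                          xyFromCell(case$raster, case$src),
                                          snapRadius = 0))
    extra <- randomFrictionCase(seed + 100, nSrc = 1)$src
    if (!is.finite(case$cost[extra])) next
    both <- rbind(case$src, extra)
    t2 <- gridValues(cumulativeTravelTime(case$raster,
                                          xyFromCell(case$raster, both),
                                          snapRadius = 0))
    expect_true(all(t2 <= t1 + 1e-12))
  }
})

test_that("scaling friction scales every finite travel time exactly", {
  case <- randomFrictionCase(20)
  xy <- xyFromCell(case$raster, case$src)
  t1 <- gridValues(cumulativeTravelTime(case$raster, xy, snapRadius = 0))
  lambda <- 3.7
  scaled <- gridRaster(case$cost * lambda, 100)
  t2 <- gridValues(cumulativeTravelTime(scaled, xy, snapRadius = 0))
  fin <- is.finite(t1)
  expect_equal(t2[fin], lambda * t1[fin], tolerance = 1e-12)
  expect_true(all(is.infinite(t2[!fin])))
})

test_that("uniform friction gives 8-connected chamfer distance", {
  n <- 15
  r <- gridRaster(matrix(1, n, n), 100)  # 1 s/m everywhere
  src <- cbind(4, 5)
  tt <- gridValues(cumulativeTravelTime(r, xyFromCell(r, src)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(i - src[1]); dc <- abs(j - src[2])
    chamfer <- 100 * (sqrt(2) * min(dr, dc) + abs(dr - dc))
    expect_equal(tt[i, j], chamfer / 60, tolerance = 1e-12)
  }
})

test_that("sources on impassable cells snap within the radius or drop", {
  cost <- matrix(1, 5, 5)
  cost[3, 3] <- Inf
  r <- gridRaster(cost, 100)
  xy <- xyFromCell(r, cbind(3, 3))
  tt <- cumulativeTravelTime(r, xy, snapRadius = 150)
  expect_equal(sum(gridValues(tt) == 0), 1)  # snapped to one neighbour
  expect_error(suppressWarnings(cumulativeTravelTime(r, xy, snapRadius = 0)),
               "no usable source")
  allBlocked <- gridRaster(matrix(Inf, 3, 3), 100)
  expect_error(suppressWarnings(
    cumulativeTravelTime(allBlocked, cbind(150, 150), snapRadius = 1000)),
    "no usable source")
})

test_that("band classification uses closed upper boundaries", {
  r <- gridRaster(matrix(c(0, 30, 30.01, 60, 60.5, 120, 121, Inf, 15), 3), 1)
  b <- gridValues(bandClassify(r))
  expect_equal(as.vector(b), c(1, 1, 2, 2, 3, 3, 4, 4, 1))
  expect_error(bandClassify(r, breaks = c(60, 30)), "increasing")
})

test_that("travel-time change is signed, NA-guarded and monotone under growth", {
  case <- randomFrictionCase(30, nSrc = 1)
  xy1 <- xyFromCell(case$raster, case$src)
  tt1 <- cumulativeTravelTime(case$raster, xy1, snapRadius = 0)
  expect_equal(max(abs(gridValues(travelTimeChange(tt1, tt1))),
                   na.rm = TRUE), 0)
  extra <- randomFrictionCase(31, nSrc = 1)$src
  if (is.finite(case$cost[extra])) {
    tt2 <- cumulativeTravelTime(case$raster, rbind(xy1,
                                xyFromCell(case$raster, extra)),
                                snapRadius = 0)
    ch <- travelTimeChange(tt1, tt2)
    expect_true(all(gridValues(ch) <= 1e-12, na.rm = TRUE))
    reach <- attr(gridValues(ch), "reachability")
    expect_true(all(reach[is.infinite(gridValues(tt1)) &
                            is.infinite(gridValues(tt2))] == "neither"))
  }
  wrongGrid <- cumulativeTravelTime(gridRaster(matrix(1, 4, 4), 100),
                                    cbind(50, 50))
  expect_error(travelTimeChange(tt1, wrongGrid), "do not match")
})

test_that("speed config validates and reads from YAML", {
  expect_error(speedConfig(walkKmh = c(grassland = -1)), "positive")
  f <- system.file("extdata", "speeds.yaml", package = "hmisaccess")
  cfg <- readSpeedConfig(f)
  expect_equal(cfg@walkKmh[["grassland"]], 5)
  expect_equal(cfg@roadKmh[["primary"]], 80)
  expect_true(cfg@waterImpassable)
})
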