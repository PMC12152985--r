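test_that("provision flags are exactly count > 0 and cube is complete", {
  reg <- tinyRegistry()
  rec <- data.frame(facility_id = c("f1", "f1", "f2"),
                    year = c(2016, 2017, 2020),
                    indicator = c("malaria", "malaria", "birth"),
                    count = c(0, 1, 3))
  cube <- provisionCube(readServiceRecords(rec), reg)
  m <- SummarizedExperiment::assay(cube, "malaria")
  expect_false(m["f1", "2016"])  # zero count is not provision
  expect_true(m["f1", "2017"])   # one is
  expect_equal(dim(cube), c(3L, 7L))
  # f3 absent from records entirely: never operational
  expect_false(any(operationalMatrix(cube)["f3", ]))
  expect_error(provisionCube(data.frame(facility_id = "zz", year = 2016,
                                        indicator = "birth", count = 1), reg),
               "unknown facility")
})

test_that("percentProviding matches an independent tally on a synthetic fixture", {
  sc <- smallScenario(seed = 31, n = 10L)
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  rec <- generateServiceHistories(reg, sc)$records
  cube <- provisionCube(readServiceRecords(rec), reg)
  for (y in STUDY_YEARS) {
    for (ind in SERVICE_INDICATORS) {
      for (tp in c(NA, FACILITY_TYPES)) {
        # independent group-by tally straight off the records table
        elig <- if (ind == "caesarean") "Hospital" else FACILITY_TYPES
        ids <- reg$facility_id[reg$type %in% elig &
                                 (is.na(tp) | reg$type == tp)]
        yr <- rec[rec$year == y & rec$facility_id %in% ids &
                    rec$count > 0, ]
        den <- length(unique(yr$facility_id))
        num <- length(unique(yr$facility_id[yr$indicator == ind]))
        want <- if (den == 0) NA_real_ else 100 * num / den
        got <- suppressWarnings(
          percentProviding(cube, y, ind, if (is.na(tp)) NULL else tp))
        expect_equal(got, want,
                     info = sprintf("%d %s %s", y, ind, tp))
      }
    }
  }
})

test_that("percentProviding handles arithmetic and empty denominators", {
  # 2 of 4 operational CHPS provide antenatal -> 50
  spec <- list(
    c1 = list(`2016` = c("outpatient", "antenatal")),
    c2 = list(`2016` = c("outpatient", "antenatal")),
    c3 = list(`2016` = "outpatient"),
    c4 = list(`2016` = "outpatient"))
  cube <- cubeFromSpec(spec)
  expect_equal(percentProviding(cube, 2016, "antenatal"), 50)
  expect_equal(percentProviding(cube, 2016, "outpatient"), 100)
  expect_warning(p <- percentProviding(cube, 2017, "antenatal"),
                 "no operational")
  expect_true(is.na(p))
})

test_that("caesarean percentages are assessed among hospitals only", {
  reg <- tinyRegistry()  # f3 is the only hospital
  rec <- data.frame(facility_id = c("f1", "f3", "f3"),
                    year = 2016,
                    indicator = c("outpatient", "outpatient", "caesarean"),
                    count = 1)
  cube <- provisionCube(readServiceRecords(rec), reg)
  # denominator is 1 operational hospital, not the 2 operational facilities
  expect_equal(percentProviding(cube, 2016, "caesarean"), 100)
})

test_that("classifier reproduces the class definitions on canonical histories", {
  yrs <- as.character(STUDY_YEARS)
  mk <- function(byYear) cubeFromSpec(list(f = byYear))
  cls <- function(byYear) as.character(classifyFacilities(mk(byYear))[["f"]])
  allYears <- function(ind) setNames(rep(list(ind), 7), yrs)
  expect_equal(cls(allYears("outpatient")), "existing_unchanged")
  expect_equal(cls(list()), "no_service")
  expect_equal(cls(list(`2016` = "birth")), "closed")
  expect_equal(cls(list(`2022` = "birth")), "newly_operational")
  expect_equal(cls(list(`2018` = "birth", `2019` = "birth")), "oscillating")
  inc <- allYears("outpatient"); inc$`2022` <- c("outpatient", "antenatal")
  expect_equal(cls(inc), "existing_increased")
  dec <- allYears(c("outpatient", "antenatal")); dec$`2022` <- "outpatient"
  expect_equal(cls(dec), "existing_decreased")
  vr <- allYears("outpatient"); vr$`2019` <- c("outpatient", "malaria")
  expect_equal(cls(vr), "existing_varying")
  gap <- allYears("outpatient"); gap$`2019` <- NULL
  expect_equal(cls(gap), "other_intermittent")
})

test_that("all 128 operational patterns receive exactly one top-level class", {
  # brute-force enumeration of presence/absence per year
  topLevel <- c(closed = "closed", newly_operational = "newly_operational",
                no_service = "no_service", oscillating = "oscillating")
  seen <- character(128)
  for (k in 0:127) {
    bits <- as.logical(bitwAnd(k, 2^(0:6)))
    byYear <- setNames(lapply(bits, function(b) if (b) "outpatient"),
                       STUDY_YEARS)
    byYear <- byYear[!vapply(byYear, is.null, TRUE)]
    got <- as.character(classifyFacilities(cubeFromSpec(list(f = byYear)))[["f"]])
    # independent rule evaluation straight from the definitions
    want <- if (!any(bits)) "no_service"
      else if (bits[1] && !bits[7]) "closed"
      else if (!bits[1] && bits[7]) "newly_operational"
      else if (!bits[1] && !bits[7]) "oscillating"
      else if (all(bits)) "existing_unchanged"  # constant single service
      else "other_intermittent"
    expect_equal(got, want, info = paste("pattern", k))
    seen[k + 1] <- got
  }
  expect_equal(sum(seen == "no_service"), 1)
  expect_equal(sum(seen == "existing_unchanged"), 1)
  # 2^5 combinations of intermediate years for each endpoint combination
  expect_equal(sum(seen == "closed"), 32)
  expect_equal(sum(seen == "newly_operational"), 32)
  expect_equal(sum(seen == "oscillating"), 31)
  expect_equal(sum(seen == "other_intermittent"), 31)
})

test_that("noise-free synthetic archetypes are recovered without error", {
  sc <- regionScenario(nRows = 60, nCols = 60, nFacilities = 1000L,
                       seed = 17)
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  hist <- generateServiceHistories(reg, sc)
  cube <- provisionCube(readServiceRecords(hist$records), reg)
  cls <- classifyFacilities(cube)
  gt <- hist$groundTruth
  expect_equal(sum(as.character(cls[gt$facility_id]) != gt$archetype), 0)
})

test_that("class distribution partitions facilities and tracks the mix", {
  sc <- regionScenario(nRows = 60, nCols = 60, nFacilities = 1000L, seed = 19,
                       archetypeMix = c(existing_unchanged = 0.4,
                                        newly_operational = 0.2,
                                        closed = 0.1, oscillating = 0.1,
                                        no_service = 0.2))
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  hist <- generateServiceHistories(reg, sc)
  cube <- provisionCube(readServiceRecords(hist$records), reg)
  cls <- classifyFacilities(cube)
  dist <- classDistribution(cls, reg)
  all <- dist[dist$facility_type == "All", ]
  expect_equal(sum(all$count), 1000L)
  expect_equal(sum(all$percent), 100, tolerance = 1e-9)
  for (nm in names(sc@archetypeMix)) {
    expect_lt(abs(all$percent[all$class == nm] / 100 - sc@archetypeMix[[nm]]),
              0.03)
  }
  # single facility: its class at 100%
  one <- classDistribution(cls[1], reg[reg$facility_id == names(cls)[1], ])
  expect_equal(one$percent[one$facility_type == "All" & one$count > 0], 100)
})

test_that("ownership x type table reproduces published composition arithmetic", {
  counts <- rbind(CHPS = c(344, 3, 50), HealthCentre = c(117, 0, 0),
                  Hospital = c(14, 5, 15), MaternityHome = c(0, 0, 11))
  colnames(counts) <- OWNERSHIP_LEVELS
  tab <- ownershipTypeTable(counts)
  expect_equal(tab$total, 559)
  expect_equal(round(tab$ownershipShare[["Government"]], 1), 85.0)
  expect_equal(round(tab$ownershipShare[["Private"]], 1), 13.6)
  expect_equal(round(tab$ownershipShare[["FaithBased"]], 1), 1.4)
  expect_equal(round(tab$typeShare[["CHPS"]], 1), 71.0)
  expect_equal(round(tab$typeShare[["HealthCentre"]], 1), 20.9)
  expect_equal(round(tab$typeShare[["Hospital"]], 1), 6.1)
  expect_equal(round(tab$rowPercent["CHPS", "Government"], 1), 86.6)
  expect_equal(round(tab$colPercent["CHPS", "Private"], 1), 65.8)
  expect_equal(round(tab$colPercent["HealthCentre", "Government"], 1), 24.6)
  # registry input agrees with matrix input
  reg <- tinyRegistry()
  tab2 <- ownershipTypeTable(reg)
  expect_equal(sum(tab2$counts), 3)
  expect_equal(tab2$rowPercent["CHPS", "Government"], 100)
})

test_that("fisherExact exact mode matches brute-force enumeration to 1e-12", {
  expect_equal(fisherExact(matrix(c(10, 10, 10, 10), 2))$p.value, 1.0)
  # spec-style strongly associated 2x2
  t2 <- matrix(c(1, 11, 9, 3), 2)
  expect_equal(fisherExact(t2)$p.value, bruteFisher2xc(t2), tolerance = 1e-12)
  # all 2x2 tables with n <= 12, plus random 2x2 / 2x3 with n <= 30
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (dd in 0:4) {
    tab <- matrix(c(a, cc, b, dd), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact(tab)$p.value, bruteFisher2xc(tab),
                 tolerance = 1e-12, info = paste(a, b, cc, dd))
  }
  set.seed(5)
  for (rep in 1:60) {
    nc <- sample(2:3, 1)
    tab <- matrix(stats::rmultinom(1, sample(6:30, 1), runif(2 * nc)), 2, nc)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisherExact(tab)$p.value, bruteFisher2xc(tab),
                 tolerance = 1e-12)
    # independent cross-check against the reference implementation
    expect_equal(fisherExact(tab)$p.value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("fisherExact validates input and falls back to seeded Monte Carlo", {
  expect_error(fisherExact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(fisherExact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  big <- matrix(c(50, 60, 40, 30, 70, 20, 30, 40, 50, 60, 20, 10), 3, 4)
  r1 <- fisherExact(big, cap = 500, nDraws = 2000L, seed = 42L)
  r2 <- fisherExact(big, cap = 500, nDraws = 2000L, seed = 42L)
  expect_equal(r1$method, "monte_carlo")
  expect_identical(r1$p.value, r2$p.value)     # seeded: reproducible
  expect_equal(r1$nDraws, 2000L)
  # MC approximates the exact answer on a small table
  small <- matrix(c(8, 2, 3, 9), 2)
  pe <- fisherExact(small)$p.value
  pm <- fisherExact(small, cap = 1, nDraws = 20000L, seed = 7L)$p.value
  expect_lt(abs(pe - pm), 0.02)
})

test_that("ownership-functionality association test runs on synthetic data", {
  sc <- smallScenario(seed = 23, n = 150L)
  reg <- generateFacilities(sc, generateDistricts(sc))$registry
  hist <- generateServiceHistories(reg, sc)
  cube <- provisionCube(readServiceRecords(hist$records), reg)
  cls <- classifyFacilities(cube)
  res <- ownershipFunctionalityTest(cls, reg, seed = 3L)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  expect_true(res$method %in% c("exact_enumeration", "monte_carlo"))
  expect_equal(sum(res$table), 150)
})
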