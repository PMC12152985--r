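#' Validate a real-data input configuration
#'
#' Real-data mode expects a named list of paths; this checks presence of every
#' required field before any stage runs and reports the missing fields by
#' name.
#'
#' @param paths named list with \code{registry}, \code{records},
#'   \code{districts}, \code{dem}, \code{landcover}, \code{population},
#'   \code{roads} (optional: \code{water}, \code{speeds}).
#' @return invisibly \code{TRUE}; errors otherwise.
#' @export
validateInputPaths <- function(paths) {
  need <- c("registry", "records", "districts", "dem", "landcover",
            "population", "roads")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("input configuration missing field(s): ",
         paste(missing, collapse = ", "))
  absent <- need[!vapply(paths[need], file.exists, TRUE)]
  if (length(absent))
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", absent, unlist(paths[absent])),
               collapse = ", "))
  invisible(TRUE)
}

.md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Run the full access-analysis pipeline
#'
#' Orchestrates generate/load -> coordinate QA -> provision cube and
#' functional classification -> friction and travel time -> population
#' projection -> coverage by band, writing CSV/JSON outputs and a run
#' manifest. Any stage failure aborts the downstream stages; the manifest
#' records per-stage status and row/cell counts, the seed, a configuration
#' hash and output checksums, so two runs with the same configuration are
#' byte-identical.
#'
#' @param config a \linkS4class{RegionScenario} (synthetic mode) or a named
#'   list of input paths (real-data mode, see
#'   \code{\link{validateInputPaths}}).
#' @param outDir output directory.
#' @param speedCfg a \linkS4class{SpeedConfig}.
#' @param projCfg a \linkS4class{ProjectionConfig}; defaults from the
#'   scenario in synthetic mode.
#' @param breaks travel-time band boundaries, minutes.
#' @param years years for the coverage trend.
#' @param qaTolerance boundary tolerance in metres for location QA.
#' @param writeRasters also write per-service travel-time rasters for the
#'   first and last year (ASCII grid).
#' @return the manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config, outDir, speedCfg = speedConfig(),
                        projCfg = NULL, breaks = c(30, 60, 120),
                        years = STUDY_YEARS, qaTolerance = 2000,
                        writeRasters = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- is(config, "RegionScenario")
  if (!synthetic) validateInputPaths(config)
  manifest <- list(mode = if (synthetic) "synthetic" else "real",
                   seed = if (synthetic) config@seed else NA_integer_,
                   configHash = .md5OfObject(
                     if (synthetic) .scenarioAsList(config) else config),
                   bandBreaks = breaks, stages = list())
  note <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(status = "ok"), list(...))
  }
  p <- function(f) file.path(outDir, f)
  failed <- FALSE
  runStage <- function(name, expr) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      failed <<- TRUE
      NULL
    })
  }

  inputs <- runStage("inputs", {
    if (synthetic) {
      region <- generateRegion(config)
      if (is.null(projCfg))
        projCfg <- projectionConfig(baselineYear = 2021L,
                                     growthRatePct = config@growthRatePct,
                                     subgroupProps = config@subgroupProps)
      note("inputs", facilities = nrow(region@registry),
           records = nrow(region@records),
           cells = prod(gridDim(region@dem)))
      list(registry = region@registry, records = region@records,
           districts = region@districts, dem = region@dem,
           landcover = region@landcover, population = region@population,
           roads = region@roads, water = region@water)
    } else {
      if (is.null(projCfg)) projCfg <- projectionConfig()
      reg <- readFacilityRegistry(config$registry)
      rec <- readServiceRecords(config$records)
      note("inputs", facilities = nrow(reg), records = nrow(rec))
      list(registry = reg, records = rec,
           districts = readDistricts(config$districts),
           dem = readAsciiGrid(config$dem),
           landcover = readAsciiGrid(config$landcover),
           population = readAsciiGrid(config$population),
           roads = readGeoJSON(config$roads),
           water = if (!is.null(config$water)) readGeoJSON(config$water)
                   else list())
    }
  })

  qaRes <- runStage("qa", {
    res <- suppressWarnings(
      qaLocations(inputs$registry, inputs$districts, tolerance = qaTolerance))
    utils::write.csv(res$qa, p("qa_report.csv"), row.names = FALSE)
    note("qa", facilities = nrow(res$qa),
         repaired = sum(startsWith(res$qa$status, "repaired")),
         unresolved = sum(res$qa$status == "unresolved"))
    res
  })

  classRes <- runStage("classify", {
    cube <- provisionCube(readServiceRecords(inputs$records),
                          qaRes$registry, years = years)
    classes <- classifyFacilities(cube)
    dist <- classDistribution(classes, qaRes$registry)
    trends <- provisionTrends(cube)
    ott <- ownershipTypeTable(qaRes$registry)
    fisher <- ownershipFunctionalityTest(classes, qaRes$registry)
    utils::write.csv(data.frame(facility_id = names(classes),
                                class = as.character(classes)),
                     p("facility_classes.csv"), row.names = FALSE)
    utils::write.csv(dist, p("class_distribution.csv"), row.names = FALSE)
    utils::write.csv(trends, p("provision_percent.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ott$counts), p("ownership_type_counts.csv"))
    jsonlite::write_json(
      list(p_value = fisher$p.value, method = fisher$method,
           dim = fisher$dim), p("fisher.json"), auto_unbox = TRUE, digits = NA)
    note("classify", facilities = length(classes),
         fisher_p = fisher$p.value)
    list(cube = cube, classes = classes)
  })

  coverage <- runStage("coverage", {
    fr <- buildFriction(inputs$landcover, inputs$dem, inputs$roads,
                        inputs$water, speedCfg)
    cov <- coverageTrend(classRes$cube, fr, inputs$population, projCfg,
                         years = years, breaks = breaks, qa = qaRes$qa)
    utils::write.csv(cov, p("coverage.csv"), row.names = FALSE)
    if (writeRasters) {
      for (ind in SERVICE_INDICATORS) {
        for (y in range(years)) {
          src <- serviceSources(classRes$cube, ind, y, qaRes$qa)
          if (nrow(src) == 0L) next
          tt <- cumulativeTravelTime(fr, src, indicator = ind, year = y)
          writeAsciiGrid(tt, p(sprintf("traveltime_%s_%d.asc", ind, y)))
        }
      }
    }
    note("coverage", rows = nrow(cov),
         frictionCells = prod(gridDim(fr)))
    cov
  })

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$outputs <- as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                              basename(outputs)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.scenarioAsList <- function(sc) {
  list(nRows = sc@nRows, nCols = sc@nCols, cellSize = sc@cellSize,
       seed = sc@seed, nFacilities = sc@nFacilities,
       typeMix = sc@typeMix, ownershipMix = sc@ownershipMix,
       archetypeMix = sc@archetypeMix, coordErrorRate = sc@coordErrorRate,
       totalPopulation = sc@totalPopulation,
       growthRatePct = sc@growthRatePct,
       subgroupProps = sc@subgroupProps, nDistricts = sc@nDistricts,
       waterEnabled = sc@waterEnabled)
}
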