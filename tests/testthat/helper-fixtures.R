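# Shared fixtures: small scenarios and hand-built tables used across files.

smallScenario <- function(seed = 3L, n = 40L, nRows = 60L, nCols = 60L, ...) {
  regionScenario(nRows = nRows, nCols = nCols, nFacilities = n, seed = seed,
                 ...)
}

# three-facility registry covering the enum values
tinyRegistry <- function() {
  data.frame(
    facility_id = c("f1", "f2", "f3"),
    name = c("Alpha CHPS", "Beta HC", "Gamma Hosp"),
    type = c("CHPS", "HealthCentre", "Hospital"),
    ownership = c("Government", "FaithBased", "Private"),
    district_id = "D01",
    x = c(150, 250, 350), y = c(150, 250, 350),
    stringsAsFactors = FALSE)
}

# a provision cube built from explicit per-facility year/indicator presence;
# spec: named list facility_id -> list(year -> character vector of indicators)
cubeFromSpec <- function(spec, registry = NULL) {
  if (is.null(registry)) {
    ids <- names(spec)
    registry <- data.frame(
      facility_id = ids, name = ids, type = "CHPS",
      ownership = "Government", district_id = "D01",
      x = seq_along(ids) * 100, y = seq_along(ids) * 100,
      stringsAsFactors = FALSE)
  }
  rows <- list()
  for (f in names(spec)) {
    for (y in names(spec[[f]])) {
      for (ind in spec[[f]][[y]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          facility_id = f, year = as.integer(y), indicator = ind, count = 1L)
      }
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(facility_id = character(), year = integer(),
               indicator = character(), count = integer())
  provisionCube(readServiceRecords(rec), registry)
}

# independent brute-force Fisher p-value for 2 x c tables: enumerate the free
# first row directly and compute probabilities with choose()
bruteFisher2xc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  prob <- function(row1) prod(choose(cs, row1)) / choose(n, rs[1])
  ranges <- lapply(cs, function(m) 0:m)
  grid <- do.call(expand.grid, ranges)
  grid <- grid[rowSums(grid) == rs[1], , drop = FALSE]
  pObs <- prob(as.integer(tab[1, ]))
  ps <- apply(grid, 1, function(r) prob(as.integer(r)))
  sum(ps[ps <= pObs * (1 + 1e-7)])
}

# brute-force multi-source grid shortest path via igraph (independent oracle)
igraphTravelTime <- function(cost, cellSize, srcCells) {
  nr <- nrow(cost); nc <- ncol(cost)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- list(); wts <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.finite(cost[r, c])) next
    for (k in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
      r2 <- r + k[1]; c2 <- c + k[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.finite(cost[r2, c2])) next
      d <- cellSize * if (k[1] != 0 && k[2] != 0) sqrt(2) else 1
      edges[[length(edges) + 1L]] <- c(id(r, c), id(r2, c2))
      wts[[length(wts) + 1L]] <- d * (cost[r, c] + cost[r2, c2]) / 2
    }
  }
  g <- igraph::make_empty_graph(nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, unlist(edges))
  igraph::E(g)$weight <- unlist(wts)
  dm <- igraph::distances(g, v = id(srcCells[, 1], srcCells[, 2]))
  matrix(apply(dm, 2, min), nr, nc) / 60
}

# random finite/impassable friction grid plus valid source cells
randomFrictionCase <- function(seed, nr = 20, nc = 20, nSrc = 2,
                               pBlocked = 0.05) {
  set.seed(seed)
  cost <- matrix(stats::runif(nr * nc, 0.1, 2), nr, nc)
  cost[sample.int(nr * nc, round(pBlocked * nr * nc))] <- Inf
  repeat {
    src <- cbind(sample.int(nr, nSrc, replace = TRUE),
                 sample.int(nc, nSrc, replace = TRUE))
    if (all(is.finite(cost[src]))) break
  }
  list(raster = gridRaster(cost, 100), cost = cost, src = src)
}
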