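#' Build the facility x year x indicator provision cube
#'
#' A facility provides a service in a year exactly when its aggregated count
#' for that indicator and year is greater than zero; absent records mean not
#' provided. The result is complete over registry x years x indicators.
#'
#' @param records validated service-record table
#'   (\code{\link{readServiceRecords}}).
#' @param registry validated facility registry; its columns are carried into
#'   \code{rowData}.
#' @param years study years (columns of the cube).
#' @return A \linkS4class{ProvisionCube}.
#' @examples
#' reg <- data.frame(facility_id = "f1", name = "f1", type = "CHPS",
#'                   ownership = "Government", district_id = "D01",
#'                   x = 0, y = 0)
#' rec <- data.frame(facility_id = "f1", year = 2016,
#'                   indicator = "malaria", count = 4)
#' cube <- provisionCube(readServiceRecords(rec), reg)
#' operationalMatrix(cube)["f1", "2016"]
#' @export
provisionCube <- function(records, registry, years = STUDY_YEARS) {
  ids <- registry$facility_id
  stranger <- setdiff(unique(records$facility_id), ids)
  if (length(stranger))
    stop("service records reference unknown facility: ",
         paste(utils::head(stranger, 5), collapse = ", "))
  assays <- lapply(SERVICE_INDICATORS, function(ind) {
    m <- matrix(FALSE, length(ids), length(years),
                dimnames = list(ids, years))
    sub <- records[records$indicator == ind & records$count > 0, , drop = FALSE]
    if (nrow(sub))
      m[cbind(match(sub$facility_id, ids), match(sub$year, years))] <- TRUE
    m
  })
  names(assays) <- SERVICE_INDICATORS
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(registry, row.names = ids),
    colData = S4Vectors::DataFrame(year = as.integer(years),
                                   row.names = as.character(years)))
  new("ProvisionCube", se)
}

#' Operational status per facility and year
#'
#' A facility is operational in a year when at least one of the six studied
#' indicators was provided that year.
#'
#' @param cube a \linkS4class{ProvisionCube}.
#' @return logical facility x year matrix.
#' @export
operationalMatrix <- function(cube) {
  Reduce(`|`, lapply(SERVICE_INDICATORS,
                     function(i) SummarizedExperiment::assay(cube, i)))
}

#' @rdname provisionCube
#' @param cube a \linkS4class{ProvisionCube}.
#' @export
cubeRegistry <- function(cube) {
  as.data.frame(SummarizedExperiment::rowData(cube))
}

# facility types whose denominators are eligible for an indicator; caesarean
# coverage is assessed among hospitals only
.eligibleTypes <- function(indicator) {
  if (identical(indicator, "caesarean")) "Hospital" else FACILITY_TYPES
}

#' Percentage of operational facilities providing a service
#'
#' Numerator: facilities (optionally of one type) providing the indicator in
#' the year. Denominator: operational facilities of eligible type that year.
#' Caesarean percentages are computed among hospitals only. A zero denominator
#' yields \code{NA} with a warning.
#'
#' @param cube a \linkS4class{ProvisionCube}.
#' @param year year within the cube.
#' @param indicator one of \code{SERVICE_INDICATORS}.
#' @param facilityType optional facility type restricting both numerator and
#'   denominator.
#' @return percentage in [0, 100], or \code{NA}.
#' @export
percentProviding <- function(cube, year, indicator, facilityType = NULL) {
  stopifnot(indicator %in% SERVICE_INDICATORS)
  y <- as.character(year)
  if (!y %in% colnames(cube)) stop("year ", year, " not in cube")
  types <- cubeRegistry(cube)$type
  keep <- types %in% .eligibleTypes(indicator)
  if (!is.null(facilityType)) keep <- keep & types == facilityType
  op <- operationalMatrix(cube)[keep, y]
  prov <- SummarizedExperiment::assay(cube, indicator)[keep, y]
  den <- sum(op)
  if (den == 0) {
    warning("no operational facilities for ", indicator, " in ", year)
    return(NA_real_)
  }
  100 * sum(prov & op) / den
}

#' Yearly provision-percentage table across indicators and types
#'
#' Long table of \code{\link{percentProviding}} over all years and indicators,
#' overall and per facility type — the temporal-trend summary.
#'
#' @param cube a \linkS4class{ProvisionCube}.
#' @return \code{data.frame} with year, indicator, facility_type ("All" for
#'   the overall row) and percent.
#' @export
provisionTrends <- function(cube) {
  years <- colnames(cube)
  grid <- expand.grid(year = as.integer(years),
                      indicator = SERVICE_INDICATORS,
                      facility_type = c("All", FACILITY_TYPES),
                      stringsAsFactors = FALSE)
  grid$percent <- suppressWarnings(vapply(seq_len(nrow(grid)), function(i) {
    tp <- grid$facility_type[i]
    percentProviding(cube, grid$year[i], grid$indicator[i],
                     if (tp == "All") NULL else tp)
  }, 0))
  grid
}

# classify one facility's 7-year presence history (years x indicators matrix)
.classifyHistory <- function(pres) {
  op <- rowSums(pres) > 0
  nY <- length(op)
  if (!any(op)) return("no_service")
  first <- op[1]; last <- op[nY]
  if (first && !last) return("closed")
  if (!first && last) return("newly_operational")
  if (!first && !last) return("oscillating")
  if (!all(op)) return("other_intermittent")
  sets <- apply(pres, 1, function(r) paste(which(r), collapse = ","))
  n16 <- sum(pres[1, ]); n22 <- sum(pres[nY, ])
  if (all(sets == sets[1])) return("existing_unchanged")
  if (n22 > n16) return("existing_increased")
  if (n16 > n22) return("existing_decreased")
  if (sets[1] == sets[nY]) return("existing_varying")
  # same cardinality but a different service set at the endpoints: the set
  # composition varied even though its size did not
  "existing_varying"
}

#' Classify facilities into spatio-temporal functional classes
#'
#' Applies the rule cascade per facility: \code{no_service} (never provided
#' any service), \code{closed} (operational in the first year, not the last),
#' \code{newly_operational} (the reverse), \code{oscillating} (operational
#' only in intermediate years), and \code{existing} (operational every year)
#' sub-categorised by the indicator-set trajectory: \code{unchanged} (same
#' set all years), \code{increased}/\code{decreased} (strictly more/fewer
#' services in the last year than the first), \code{varying} (same endpoint
#' sets, intermediate variation). Facilities operational at both endpoints
#' with a non-operational year in between fall in the residual
#' \code{other_intermittent} class.
#'
#' @param cube a \linkS4class{ProvisionCube}.
#' @return named factor (facility id -> class) with levels
#'   \code{FUNCTIONAL_CLASSES}.
#' @export
classifyFacilities <- function(cube) {
  ids <- rownames(cube)
  arr <- vapply(SERVICE_INDICATORS,
                function(i) SummarizedExperiment::assay(cube, i),
                matrix(TRUE, nrow(cube), ncol(cube)))
  cls <- vapply(seq_along(ids),
                function(f) .classifyHistory(arr[f, , , drop = TRUE]), "")
  factor(stats::setNames(cls, ids), levels = FUNCTIONAL_CLASSES)
}

#' Distribution of functional classes
#'
#' Counts and percentages per class, overall and by facility type; per-group
#' percentages sum to 100 (up to rounding).
#'
#' @param classes factor from \code{\link{classifyFacilities}} (names are
#'   facility ids).
#' @param registry facility registry.
#' @return \code{data.frame} with facility_type ("All" for overall), class,
#'   count, percent.
#' @export
classDistribution <- function(classes, registry) {
  type <- registry$type[match(names(classes), registry$facility_id)]
  one <- function(label, keep) {
    tab <- table(classes[keep])
    data.frame(facility_type = label, class = names(tab),
               count = as.integer(tab),
               percent = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab)
                         else rep(NA_real_, length(tab)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("All", rep(TRUE, length(classes))),
               do.call(rbind, lapply(FACILITY_TYPES,
                                     function(tp) one(tp, type == tp))))
  rownames(out) <- NULL
  out
}

#' Ownership x facility-type composition table
#'
#' Cross-tabulates facility type against ownership and derives the published
#' composition percentages: within-type ownership shares (row percents),
#' within-ownership type shares (column percents), and overall marginal
#' shares.
#'
#' @param registry facility registry, or an already-tabulated type x ownership
#'   count matrix.
#' @return list with \code{counts}, \code{rowPercent} (ownership within
#'   type), \code{colPercent} (type within ownership), \code{typeShare} and
#'   \code{ownershipShare} (marginals, percent of all facilities), and
#'   \code{total}.
#' @examples
#' counts <- rbind(CHPS = c(344, 3, 50), HealthCentre = c(117, 0, 0),
#'                 Hospital = c(14, 5, 15), MaternityHome = c(0, 0, 11))
#' colnames(counts) <- c("Government", "FaithBased", "Private")
#' round(ownershipTypeTable(counts)$ownershipShare["Government"], 1)  # 85.0
#' @export
ownershipTypeTable <- function(registry) {
  counts <- if (is.matrix(registry)) registry else
    unclass(table(factor(registry$type, FACILITY_TYPES),
                  factor(registry$ownership, OWNERSHIP_LEVELS)))
  counts <- as.matrix(counts)
  total <- sum(counts)
  rowTot <- rowSums(counts); colTot <- colSums(counts)
  rowPercent <- sweep(counts, 1, ifelse(rowTot > 0, rowTot, NA), "/") * 100
  colPercent <- sweep(counts, 2, ifelse(colTot > 0, colTot, NA), "/") * 100
  list(counts = counts,
       rowPercent = rowPercent, colPercent = colPercent,
       typeShare = 100 * rowTot / total,
       ownershipShare = 100 * colTot / total,
       total = total)
}

# log-probability of an r x c table under the fixed-margin (multivariate
# hypergeometric) null
.logProbTable <- function(tab, rs = rowSums(tab), cs = colSums(tab),
                          n = sum(tab)) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(tab + 1))
}

# enumerate all tables with the given margins, calling fn(tab) on each;
# aborts (returns FALSE) once more than cap tables have been visited
.enumTables <- function(rs, cs, fn, cap = Inf) {
  r <- length(rs); c <- length(cs)
  tab <- matrix(0L, r, c)
  count <- 0L
  rec <- function(i, j, rowLeft, colLeft) {
    if (i == r) {           # last row is forced by the column margins
      if (any(colLeft < 0)) return(TRUE)
      tab[r, ] <<- colLeft
      count <<- count + 1L
      if (count > cap) return(FALSE)
      fn(tab)
      return(TRUE)
    }
    if (j == c) {           # last cell of the row forced by the row margin
      return(rec(i + 1L, 1L, rs[i + 1L], colLeft))
    }
    if (j == c - 0L) {}     # no-op; clarity
    hi <- min(rowLeft, colLeft[j])
    for (v in 0:hi) {
      tab[i, j] <<- v
      ok <- if (j == c - 1L) {
        # last free cell in the row: remainder goes to column c
        rest <- rowLeft - v
        if (rest <= colLeft[c]) {
          tab[i, c] <<- rest
          cl <- colLeft; cl[j] <- cl[j] - v; cl[c] <- cl[c] - rest
          rec(i + 1L, 1L, if (i + 1L <= r) rs[i + 1L] else 0L, cl)
        } else TRUE
      } else {
        cl <- colLeft; cl[j] <- cl[j] - v
        rec(i, j + 1L, rowLeft - v, cl)
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }
  done <- rec(1L, 1L, rs[1L], cs)
  list(complete = done, count = count)
}

#' Fisher's exact test for r x c tables
#'
#' Tests independence of rows and columns under the fixed-margin null. Below
#' \code{cap} enumerable tables the p-value is computed by exact enumeration:
#' the sum of the probabilities of all margin-preserving tables whose
#' probability does not exceed that of the observed table (with relative tie
#' tolerance 1e-7). Larger problems fall back to a seeded Monte-Carlo
#' estimate over \code{nDraws} tables drawn with \code{\link[stats]{r2dtable}}
#' (p = (1 + #{as extreme}) / (nDraws + 1)).
#'
#' @param tab matrix of non-negative integer counts.
#' @param cap maximum number of margin-preserving tables to enumerate exactly
#'   before falling back to Monte Carlo.
#' @param nDraws Monte-Carlo draws when enumeration is abandoned.
#' @param seed integer seed for the Monte-Carlo path.
#' @return list with \code{p.value}, \code{method}
#'   (\code{"exact_enumeration"} or \code{"monte_carlo"}), \code{dim}, and
#'   for Monte-Carlo \code{nDraws} and \code{seed}.
#' @examples
#' fisherExact(matrix(c(10, 10, 10, 10), 2))$p.value  # 1
#' @export
fisherExact <- function(tab, cap = 20000, nDraws = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: all-zero row or column")
  rs <- as.integer(rowSums(tab)); cs <- as.integer(colSums(tab))
  n <- sum(tab)
  lpObs <- .logProbTable(tab, rs, cs, n)
  tieTol <- log1p(1e-7)
  acc <- new.env()
  acc$p <- 0
  res <- .enumTables(rs, cs, function(t2) {
    lp <- .logProbTable(t2, rs, cs, n)
    if (lp <= lpObs + tieTol) acc$p <- acc$p + exp(lp)
  }, cap = cap)
  if (res$complete) {
    return(list(p.value = min(1, acc$p), method = "exact_enumeration",
                dim = dim(tab), nTables = res$count))
  }
  .withSeed(seed, {
    sims <- stats::r2dtable(nDraws, rs, cs)
    lps <- vapply(sims, .logProbTable, 0, rs = rs, cs = cs, n = n)
    p <- (1 + sum(lps <= lpObs + tieTol)) / (nDraws + 1)
    list(p.value = p, method = "monte_carlo", dim = dim(tab),
         nDraws = nDraws, seed = seed)
  })
}

#' Ownership vs functionality association
#'
#' Cross-tabulates facility ownership against functional class (classes with
#' no facilities are dropped) and applies \code{\link{fisherExact}}.
#'
#' @param classes factor from \code{\link{classifyFacilities}}.
#' @param registry facility registry.
#' @param collapse optional named list mapping coarse labels to class levels
#'   to merge before testing (sparse class x ownership tables are otherwise
#'   near-degenerate); default merges the existing_* sub-classes.
#' @inheritParams fisherExact
#' @return \code{fisherExact} result plus the tested \code{table}.
#' @export
ownershipFunctionalityTest <- function(classes, registry,
    collapse = list(existing = c("existing_unchanged", "existing_increased",
                                 "existing_decreased", "existing_varying")),
    cap = 20000, nDraws = 10000L, seed = 1L) {
  lab <- as.character(classes)
  for (nm in names(collapse)) lab[lab %in% collapse[[nm]]] <- nm
  own <- registry$ownership[match(names(classes), registry$facility_id)]
  tab <- table(lab, own)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  res <- fisherExact(unclass(tab), cap = cap, nDraws = nDraws, seed = seed)
  res$table <- tab
  res
}
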