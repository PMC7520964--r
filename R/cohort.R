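## Birth-record data model: CSV schema I/O, exclusion rules with an audit
## trail, SGA derivation, and the cross-tabulations every model consumes.

.SCHEMA_REQUIRED <- c("mage", "page", "ds", "cd")
.SCHEMA_OPTIONAL <- c("birthweight_g", "gestation_days")

.emptyRecords <- function(n = 0) {
  rec <- data.frame(
    mage = rep(NA_integer_, n),
    page = rep(NA_integer_, n)
  )
  rec$ds <- rep(NA, n)
  rec$cd <- rep(NA, n)
  for (oc in nmmOutcomes()) rec[[oc]] <- rep(NA, n)
  rec$birthweight_g <- rep(NA_integer_, n)
  rec$gestation_days <- rep(NA_integer_, n)
  rec
}

#' Construct a BirthCohort from a record table
#'
#' @param records `data.frame` with (a subset of) the schema columns `mage`,
#'   `page`, `ds`, `cd`, the ten outcomes of [nmmOutcomes()],
#'   `birthweight_g`, `gestation_days`. Absent columns are filled with `NA`;
#'   flags given as 0/1 are coerced to logical.
#' @param provenance Free-text label recorded on the object.
#' @return A [BirthCohort].
#' @export
#' @examples
#' bc <- birthCohort(data.frame(mage = c(20, 30), page = c(25, 31),
#'                              ds = c(0, 0), cd = c(0, 1)))
#' nBirths(bc)
birthCohort <- function(records, provenance = "in-memory") {
  out <- .emptyRecords(nrow(records))
  known <- c(.SCHEMA_REQUIRED, nmmOutcomes(), .SCHEMA_OPTIONAL)
  for (col in intersect(names(records), known)) out[[col]] <- records[[col]]
  for (col in c("mage", "page", .SCHEMA_OPTIONAL)) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("ds", "cd", nmmOutcomes())) {
    v <- out[[col]]
    if (!is.logical(v)) v <- as.logical(as.integer(v))
    out[[col]] <- v
  }
  new("BirthCohort", records = out, provenance = provenance)
}

#' Read a birth cohort from its CSV schema
#'
#' The schema is one row per singleton birth with a mandatory header:
#' `mage,page,ds,cd,preterm,very_preterm,sga,low_apgar,nicu,antibiotics,`
#' `surfactant,prolonged_ventilation,seizures,death[,birthweight_g,gestation_days]`.
#' Empty cells are missing values; flag columns accept 0/1. Unknown columns
#' are ignored with a warning; of the schema columns only `mage` is
#' mandatory.
#'
#' @param path Path to the CSV file.
#' @param provenance Label stored on the cohort (defaults to the path).
#' @return A [BirthCohort] with one record per data row.
#' @export
readBirths <- function(path, provenance = path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  known <- c(.SCHEMA_REQUIRED, nmmOutcomes(), .SCHEMA_OPTIONAL)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown columns: ", paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  if (!"mage" %in% names(raw)) {
    stop("schema error: mandatory column 'mage' (maternal age) is absent")
  }
  parseInt <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(out) | out != floor(out)))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-integer value '%s' in column '%s', row %d",
                   v[bad[1]], col, bad[1]))
    }
    as.integer(out)
  }
  rec <- data.frame(mage = parseInt("mage"))
  for (col in c("page", .SCHEMA_OPTIONAL)) {
    if (col %in% names(raw)) rec[[col]] <- parseInt(col)
  }
  for (col in c("ds", "cd", nmmOutcomes())) {
    if (col %in% names(raw)) {
      v <- raw[[col]]
      v[v == ""] <- NA
      ok <- is.na(v) | v %in% c("0", "1", "TRUE", "FALSE")
      if (!all(ok)) {
        bad <- which(!ok)[1]
        stop(sprintf("parse error: non-boolean value '%s' in column '%s', row %d",
                     v[bad], col, bad))
      }
      rec[[col]] <- ifelse(is.na(v), NA, v %in% c("1", "TRUE"))
    }
  }
  birthCohort(rec, provenance = provenance)
}

#' Write a birth cohort in the CSV schema
#'
#' Inverse of [readBirths()]: logical flags are written as 0/1 and missing
#' values as empty cells, so a write-then-read round trip reproduces the
#' records exactly.
#'
#' @param cohort A [BirthCohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeBirths <- function(cohort, path) {
  rec <- cohort@records
  out <- rec
  for (col in c("ds", "cd", nmmOutcomes())) out[[col]] <- as.integer(rec[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the study exclusion rules with an audit trail
#'
#' Retains records whose maternal age lies in `maternalRange`, whose
#' paternal age is present and lies in `paternalRange`, and whose ten NMM
#' outcome flags are all present. Deletions are tallied in a
#' [FilterReport], each record in exactly one category, with parent-age
#' rules applied before the missing-outcome rule and maternal rules before
#' the paternal rule.
#'
#' @param cohort A [BirthCohort].
#' @param maternalRange Inclusive integer bounds for maternal age
#'   (default `c(15, 49)`).
#' @param paternalRange Inclusive integer bounds for paternal age
#'   (default `c(15, 65)`).
#' @return A list with elements `cohort` (the filtered [BirthCohort]) and
#'   `report` (the [FilterReport]).
#' @export
filterCohort <- function(cohort, maternalRange = c(15L, 49L),
                         paternalRange = c(15L, 65L)) {
  if (maternalRange[1] > maternalRange[2] || paternalRange[1] > paternalRange[2]) {
    stop("inverted age range: lower bound exceeds upper bound")
  }
  rec <- cohort@records
  nInput <- nrow(rec)
  ## maternal age is mandatory on a birth certificate, so missing values are
  ## rare; when they occur they are counted with the under-minimum category
  motherUnder <- is.na(rec$mage) | rec$mage < maternalRange[1]
  motherOver <- !is.na(rec$mage) & rec$mage > maternalRange[2]
  motherOk <- !motherUnder & !motherOver
  fatherBad <- motherOk &
    (is.na(rec$page) | rec$page < paternalRange[1] | rec$page > paternalRange[2])
  parentOk <- motherOk & !fatherBad
  outcomeMissing <- parentOk &
    Reduce(`|`, lapply(nmmOutcomes(), function(oc) is.na(rec[[oc]])))
  keep <- parentOk & !outcomeMissing
  report <- new("FilterReport",
    nInput = nInput,
    nMotherUnderMin = sum(motherUnder),
    nMotherOverMax = sum(motherOver),
    nFatherOutOfRangeOrMissing = sum(fatherBad),
    nDeletedForParentAge = sum(motherUnder) + sum(motherOver) + sum(fatherBad),
    nDeletedForMissingOutcome = sum(outcomeMissing),
    nRetained = sum(keep)
  )
  filtered <- new("BirthCohort",
    records = rec[keep, , drop = FALSE],
    provenance = paste0(cohort@provenance, " [filtered]")
  )
  rownames(filtered@records) <- NULL
  list(cohort = filtered, report = report)
}

#' Derive the small-for-gestational-age flag
#'
#' Flags a birth as SGA when its birthweight falls strictly below the
#' empirical 10th percentile of birthweights among births with the same
#' gestational length in days. The percentile uses the default empirical
#' quantile with linear interpolation between order statistics
#' (`stats::quantile` type 7). Records lacking birthweight or gestational
#' length keep their existing `sga` flag.
#'
#' @param cohort A [BirthCohort] whose records carry `birthweight_g` and
#'   `gestation_days`.
#' @return The cohort with `sga` recomputed.
#' @export
deriveSGA <- function(cohort) {
  rec <- cohort@records
  has <- !is.na(rec$birthweight_g) & !is.na(rec$gestation_days)
  if (any(has)) {
    days <- rec$gestation_days[has]
    wt <- rec$birthweight_g[has]
    thresholds <- tapply(wt, days, function(x) {
      if (length(x) < 10) {
        warning("fewer than 10 births for a gestation day; ",
                "10th-percentile threshold computed from a small cell")
      }
      quantile(x, probs = 0.1, type = 7, names = FALSE)
    })
    thr <- thresholds[as.character(days)]
    rec$sga[has] <- wt < thr
  }
  new("BirthCohort", records = rec, provenance = cohort@provenance)
}

.outcomeMatrix <- function(rec) {
  ## vapply only returns a matrix when length(FUN.VALUE) > 1, so single-row
  ## (and empty) cohorts need the shape restored explicitly
  m <- vapply(nmmOutcomes(), function(oc) as.logical(rec[[oc]]),
              logical(nrow(rec)))
  if (nrow(rec) <= 1) m <- matrix(as.logical(m), nrow(rec),
                                  length(nmmOutcomes()),
                                  dimnames = list(NULL, nmmOutcomes()))
  m
}

#' Cross-tabulate case and birth counts by one parent's age
#'
#' @param cohort A filtered [BirthCohort] (ages in range, outcomes present).
#' @param axis `"maternal"` or `"paternal"`.
#' @return An [AgeOutcomeTable] over the complete study span for the axis
#'   (maternal 15-49, paternal 15-65); ages with no births have `n = 0`.
#' @export
tabulateByAge <- function(cohort, axis = c("maternal", "paternal")) {
  axis <- match.arg(axis)
  span <- .axisSpan(axis)
  rec <- cohort@records
  age <- if (axis == "maternal") rec$mage else rec$page
  idx <- match(age, span)
  K <- length(span)
  nVec <- tabulate(idx, nbins = K)
  outc <- .outcomeMatrix(rec)
  Y <- matrix(0L, K, length(nmmOutcomes()),
              dimnames = list(NULL, nmmOutcomes()))
  nMat <- matrix(as.integer(nVec), K, length(nmmOutcomes()),
                 dimnames = list(NULL, nmmOutcomes()))
  if (nrow(rec) > 0) {
    for (k in seq_along(nmmOutcomes())) {
      ok <- !is.na(outc[, k])
      Y[, k] <- tabulate(idx[ok & outc[, k]], nbins = K)
      ## per-outcome denominators when this outcome has missing values
      if (!all(ok)) nMat[, k] <- tabulate(idx[ok], nbins = K)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Y = Y, n = nMat),
    rowData = S4Vectors::DataFrame(age = span),
    colData = S4Vectors::DataFrame(outcome = nmmOutcomes(),
                                   row.names = nmmOutcomes())
  )
  new("AgeOutcomeTable", se, axis = axis)
}

#' Cross-tabulate counts on the joint maternal x paternal age grid
#'
#' @param cohort A filtered [BirthCohort].
#' @return A [JointAgeOutcomeTable] on the complete 35 x 51 grid (1785
#'   cells); empty cells are present with `n = 0`. Its row and column
#'   marginals reproduce the two [tabulateByAge()] tables exactly.
#' @export
tabulateJoint <- function(cohort) {
  rec <- cohort@records
  grid <- expand.grid(page = .PATERNAL_SPAN, mage = .MATERNAL_SPAN)
  cellOf <- function(mage, page) {
    (match(mage, .MATERNAL_SPAN) - 1L) * length(.PATERNAL_SPAN) +
      match(page, .PATERNAL_SPAN)
  }
  idx <- cellOf(rec$mage, rec$page)
  nCells <- nrow(grid)
  nVec <- tabulate(idx, nbins = nCells)
  outc <- .outcomeMatrix(rec)
  Y <- matrix(0L, nCells, length(nmmOutcomes()),
              dimnames = list(NULL, nmmOutcomes()))
  nMat <- matrix(as.integer(nVec), nCells, length(nmmOutcomes()),
                 dimnames = list(NULL, nmmOutcomes()))
  if (nrow(rec) > 0) {
    for (k in seq_along(nmmOutcomes())) {
      ok <- !is.na(outc[, k])
      Y[, k] <- tabulate(idx[ok & outc[, k]], nbins = nCells)
      if (!all(ok)) nMat[, k] <- tabulate(idx[ok], nbins = nCells)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Y = Y, n = nMat),
    rowData = S4Vectors::DataFrame(mage = grid$mage, page = grid$page),
    colData = S4Vectors::DataFrame(outcome = nmmOutcomes(),
                                   row.names = nmmOutcomes())
  )
  new("JointAgeOutcomeTable", se)
}

#' Cross-tabulate counts by a binary chromosomal-disorder exposure
#'
#' For `exposure = "ds"` the exposed arm is `ds = TRUE`; for
#' `exposure = "cd"` it is `cd = TRUE`. DS and non-DS chromosomal disorders
#' are tabulated as separate exposures, so for `"cd"` a record with
#' `ds = TRUE, cd = FALSE` belongs to the unexposed arm.
#'
#' @param cohort A filtered [BirthCohort].
#' @param exposure `"ds"` or `"cd"`.
#' @return A [TwoByTwoTable] with per-outcome case and birth counts.
#' @export
tabulateBinary <- function(cohort, exposure = c("ds", "cd")) {
  exposure <- match.arg(exposure)
  rec <- cohort@records
  exposed <- if (exposure == "ds") rec$ds else rec$cd
  exposed[is.na(exposed)] <- FALSE
  outc <- .outcomeMatrix(rec)
  counts <- do.call(rbind, lapply(seq_along(nmmOutcomes()), function(k) {
    ok <- !is.na(outc[, k])
    data.frame(
      outcome = nmmOutcomes()[k],
      casesExposed = sum(outc[ok & exposed, k]),
      birthsExposed = sum(ok & exposed),
      casesUnexposed = sum(outc[ok & !exposed, k]),
      birthsUnexposed = sum(ok & !exposed)
    )
  }))
  new("TwoByTwoTable", exposure = exposure, counts = counts)
}

#' Extract the single-outcome count vectors a model consumes
#'
#' @param table An [AgeOutcomeTable] or [JointAgeOutcomeTable].
#' @param outcome Outcome name.
#' @return List with integer vectors `Y` and `n` over the table's rows, and
#'   the row metadata (`age`, or `mage`/`page`).
#' @export
outcomeCounts <- function(table, outcome) {
  stopifnot(outcome %in% colnames(table))
  list(
    Y = as.integer(SummarizedExperiment::assay(table, "Y")[, outcome]),
    n = as.integer(SummarizedExperiment::assay(table, "n")[, outcome]),
    rowData = as.data.frame(SummarizedExperiment::rowData(table))
  )
}
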