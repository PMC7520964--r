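#' Number of births in a cohort
#'
#' @param object A [BirthCohort].
#' @return Integer count of records.
#' @export
setGeneric("nBirths", function(object) standardGeneric("nBirths"))

#' @rdname nBirths
#' @export
setMethod("nBirths", "BirthCohort", function(object) nrow(object@records))

#' Access the per-birth record table
#'
#' @param object A [BirthCohort].
#' @return The `data.frame` of birth records.
#' @export
setGeneric("birthRecords", function(object) standardGeneric("birthRecords"))

#' @rdname birthRecords
#' @export
setMethod("birthRecords", "BirthCohort", function(object) object@records)

#' Axis of an age-indexed object
#'
#' @param object An [AgeOutcomeTable], [ORCurve] or [ShapeClassification].
#' @return `"maternal"` or `"paternal"`.
#' @export
setGeneric("ageAxis", function(object) standardGeneric("ageAxis"))

#' @rdname ageAxis
#' @export
setMethod("ageAxis", "AgeOutcomeTable", function(object) object@axis)

#' @rdname ageAxis
#' @export
setMethod("ageAxis", "ORCurve", function(object) object@axis)

#' @rdname ageAxis
#' @export
setMethod("ageAxis", "ShapeClassification", function(object) object@axis)

#' Odds-ratio curve summary table
#'
#' @param object An [ORCurve].
#' @return `data.frame` with columns `age`, `or`, `lo`, `hi`, `sig`.
#' @export
setGeneric("curveTable", function(object) standardGeneric("curveTable"))

#' @rdname curveTable
#' @export
setMethod("curveTable", "ORCurve", function(object) object@table)

#' Reference age of a standardized odds-ratio curve
#'
#' @param object An [ORCurve].
#' @return Integer reference age in years.
#' @export
setGeneric("referenceAge", function(object) standardGeneric("referenceAge"))

#' @rdname referenceAge
#' @export
setMethod("referenceAge", "ORCurve", function(object) object@referenceAge)

#' Shape label of a classified risk curve
#'
#' @param object A [ShapeClassification].
#' @return One of `"U"`, `"J"`, `"increasing"`, `"decreasing"`, `"flat"`.
#' @export
setGeneric("shapeLabel", function(object) standardGeneric("shapeLabel"))

#' @rdname shapeLabel
#' @export
setMethod("shapeLabel", "ShapeClassification", function(object) object@label)

#' Pooled draw matrix across chains
#'
#' @param object A [PosteriorDraws].
#' @return Numeric matrix with one row per stored draw (all chains stacked)
#'   and one named column per parameter.
#' @export
setGeneric("drawMatrix", function(object) standardGeneric("drawMatrix"))

#' @rdname drawMatrix
#' @export
setMethod("drawMatrix", "PosteriorDraws", function(object) {
  do.call(rbind, object@chains)
})

#' Per-chain draw matrices
#'
#' @param object A [PosteriorDraws].
#' @return List of per-chain draw matrices.
#' @export
setGeneric("chainList", function(object) standardGeneric("chainList"))

#' @rdname chainList
#' @export
setMethod("chainList", "PosteriorDraws", function(object) object@chains)

#' Filter-report counts as a named vector
#'
#' @param object A [FilterReport].
#' @return Named integer vector of the audit counts.
#' @export
setGeneric("filterCounts", function(object) standardGeneric("filterCounts"))

#' @rdname filterCounts
#' @export
setMethod("filterCounts", "FilterReport", function(object) {
  c(
    nInput = object@nInput,
    nMotherUnderMin = object@nMotherUnderMin,
    nMotherOverMax = object@nMotherOverMax,
    nFatherOutOfRangeOrMissing = object@nFatherOutOfRangeOrMissing,
    nDeletedForParentAge = object@nDeletedForParentAge,
    nDeletedForMissingOutcome = object@nDeletedForMissingOutcome,
    nRetained = object@nRetained
  )
})

setMethod("show", "BirthCohort", function(object) {
  cat("BirthCohort with", nrow(object@records), "births (",
      object@provenance, ")\n")
  rec <- object@records
  cat("  maternal age:", sum(!is.na(rec$mage)), "present;",
      "paternal age:", sum(!is.na(rec$page)), "present\n")
  cat("  DS:", sum(rec$ds, na.rm = TRUE), " CD:", sum(rec$cd, na.rm = TRUE), "\n")
})

setMethod("show", "FilterReport", function(object) {
  cts <- filterCounts(object)
  cat("FilterReport\n")
  for (nm in names(cts)) cat(sprintf("  %-28s %d\n", nm, cts[[nm]]))
})

setMethod("show", "TwoByTwoTable", function(object) {
  cat("TwoByTwoTable for exposure", object@exposure, "\n")
  print(object@counts)
})

setMethod("show", "PosteriorDraws", function(object) {
  nd <- vapply(object@chains, nrow, integer(1))
  cat("PosteriorDraws for outcome", object@outcome, "\n")
  cat("  ", length(object@chains), "chain(s) x", nd[1], "stored draws,",
      ncol(object@chains[[1]]), "parameters\n")
  cat("  axes:", paste(object@modelSpec@axes, collapse = " + "), "\n")
})

setMethod("show", "ORCurve", function(object) {
  cat("ORCurve (", object@source, "), axis", object@axis,
      ", reference age", object@referenceAge, "\n")
  print(head(object@table, 4))
  if (nrow(object@table) > 4) cat("  ...", nrow(object@table), "ages\n")
})

setMethod("show", "ShapeClassification", function(object) {
  cat("ShapeClassification:", object@label, "( axis", object@axis,
      ", trough age", object@troughAge, ")\n")
  print(object@evidence)
})

setMethod("show", "ConvergenceReport", function(object) {
  cat("ConvergenceReport: max Rhat =",
      format(max(object@stats$rhat), digits = 4),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nBirths, "births,",
      length(object@outcomes), "outcome(s), seed", object@seed, "\n")
})
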