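#' @import methods
#' @importFrom stats quantile rnorm rbinom runif median qbeta rbeta var sd
#'   plogis qlogis setNames ks.test punif aggregate
#' @importFrom utils read.csv write.csv head capture.output str
#' @importFrom grDevices adjustcolor
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom Rcpp sourceCpp
#' @useDynLib nmmbayes, .registration = TRUE
NULL

#' Canonical neonatal morbidity and mortality outcomes
#'
#' The ten binary outcomes modelled by the package, in canonical column
#' order: preterm birth (<37 weeks), very preterm birth (<32 weeks), small
#' for gestational age (lowest birthweight decile per gestational day), low
#' Apgar score (<4), NICU admission, treatment with antibiotics, treatment
#' with surfactant, prolonged (>6 h) assisted ventilation, seizures, and
#' intra-hospital death.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' nmmOutcomes()
nmmOutcomes <- function() {
  c("preterm", "very_preterm", "sga", "low_apgar", "nicu", "antibiotics",
    "surfactant", "prolonged_ventilation", "seizures", "death")
}

## Default study age spans: mothers 15-49 (35 one-year levels),
## fathers 15-65 (51 levels).
.MATERNAL_SPAN <- 15L:49L
.PATERNAL_SPAN <- 15L:65L

.axisSpan <- function(axis) {
  switch(axis,
    maternal = .MATERNAL_SPAN,
    paternal = .PATERNAL_SPAN,
    stop("unknown axis: ", axis)
  )
}

#' @title BirthCohort: a collection of per-birth records
#'
#' @description An ordered collection of singleton birth records. Each record
#' carries the parents' ages in completed years (possibly missing), the Down
#' syndrome (`ds`) and other-chromosomal-disorder (`cd`) indicator flags, the
#' ten NMM outcome flags (logical, possibly `NA`), and optionally birthweight
#' in grams and gestational length in days.
#'
#' @slot records A `data.frame` with columns `mage`, `page`, `ds`, `cd`, the
#'   ten outcome columns of [nmmOutcomes()], `birthweight_g`, and
#'   `gestation_days`.
#' @slot provenance Free-text label describing where the records came from.
#'
#' @aliases BirthCohort
#' @exportClass BirthCohort
setClass("BirthCohort",
  representation(records = "data.frame", provenance = "character"),
  prototype(provenance = "unspecified")
)

setValidity("BirthCohort", function(object) {
  rec <- object@records
  needed <- c("mage", "page", "ds", "cd", nmmOutcomes())
  missing_cols <- setdiff(needed, names(rec))
  if (length(missing_cols) > 0) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("mage", "page")) {
    v <- rec[[col]]
    if (!is.numeric(v)) return(paste(col, "must be numeric"))
    bad <- !is.na(v) & (v < 0 | v != floor(v))
    if (any(bad)) return(paste(col, "must hold non-negative integers or NA"))
  }
  for (col in c("ds", "cd", nmmOutcomes())) {
    if (!is.logical(rec[[col]])) return(paste(col, "must be logical"))
  }
  if (any(!is.na(rec$ds) & is.na(rec$cd)) || any(is.na(rec$ds) & !is.na(rec$cd))) {
    ## ds/cd may both be TRUE; both must simply be logical
  }
  vp <- rec$very_preterm
  pt <- rec$preterm
  bad <- !is.na(vp) & !is.na(pt) & vp & !pt
  if (any(bad)) {
    return("very_preterm = TRUE requires preterm = TRUE when both are present")
  }
  TRUE
})

#' @title FilterReport: audit trail of cohort exclusions
#'
#' @description Counts of records removed by [filterCohort()], one category
#' per record. Parent-age deletions take precedence over missing-outcome
#' deletions, and within parent age the maternal rules take precedence over
#' the paternal rule, so the categories partition the deleted records.
#'
#' @slot nInput Number of records before filtering.
#' @slot nMotherUnderMin Mothers younger than the maternal range.
#' @slot nMotherOverMax Mothers older than the maternal range.
#' @slot nFatherOutOfRangeOrMissing Fathers missing or out of range (among
#'   records with in-range mothers).
#' @slot nDeletedForParentAge Total parent-age deletions (sum of the above
#'   three categories).
#' @slot nDeletedForMissingOutcome Records with any NMM outcome missing,
#'   among records that survived the parent-age rules.
#' @slot nRetained Records kept.
#'
#' @exportClass FilterReport
setClass("FilterReport",
  representation(
    nInput = "integer",
    nMotherUnderMin = "integer",
    nMotherOverMax = "integer",
    nFatherOutOfRangeOrMissing = "integer",
    nDeletedForParentAge = "integer",
    nDeletedForMissingOutcome = "integer",
    nRetained = "integer"
  )
)

setValidity("FilterReport", function(object) {
  counts <- c(
    object@nInput, object@nMotherUnderMin, object@nMotherOverMax,
    object@nFatherOutOfRangeOrMissing, object@nDeletedForParentAge,
    object@nDeletedForMissingOutcome, object@nRetained
  )
  if (any(counts < 0)) return("all counts must be non-negative")
  if (object@nDeletedForParentAge !=
      object@nMotherUnderMin + object@nMotherOverMax +
      object@nFatherOutOfRangeOrMissing) {
    return("parent-age deletions must equal the sum of their categories")
  }
  if (object@nRetained != object@nInput - object@nDeletedForParentAge -
      object@nDeletedForMissingOutcome) {
    return("retained + deleted must equal input count")
  }
  TRUE
})

#' @title AgeOutcomeTable: counts cross-tabulated by one parent's age
#'
#' @description A [SummarizedExperiment::SummarizedExperiment] with one row
#' per 1-year age level (maternal 15-49 or paternal 15-65), one column per
#' outcome, and two assays: `"Y"` (case counts) and `"n"` (birth counts).
#' The `n` assay has identical columns when no outcome values were missing;
#' per-outcome denominators are supported otherwise. The age grid is always
#' complete: ages with no births appear with `n = 0`.
#'
#' @slot axis `"maternal"` or `"paternal"`.
#'
#' @exportClass AgeOutcomeTable
setClass("AgeOutcomeTable",
  contains = "SummarizedExperiment",
  representation(axis = "character")
)

.validCounts <- function(object) {
  Y <- SummarizedExperiment::assay(object, "Y")
  n <- SummarizedExperiment::assay(object, "n")
  if (any(Y < 0) || any(n < 0)) return("counts must be non-negative")
  if (any(Y > n)) return("case counts Y must not exceed birth counts n")
  TRUE
}

setValidity("AgeOutcomeTable", function(object) {
  if (!object@axis %in% c("maternal", "paternal")) {
    return("axis must be 'maternal' or 'paternal'")
  }
  ages <- SummarizedExperiment::rowData(object)$age
  if (is.null(ages)) return("rowData must carry an 'age' column")
  if (!identical(as.integer(ages), .axisSpan(object@axis))) {
    return("ages must be the complete contiguous study span for the axis")
  }
  .validCounts(object)
})

#' @title JointAgeOutcomeTable: counts on the maternal x paternal age grid
#'
#' @description A [SummarizedExperiment::SummarizedExperiment] with one row
#' per cell of the complete 35 x 51 maternal-by-paternal age grid (1785
#' rows; `rowData` columns `mage`, `page`), one column per outcome, and
#' assays `"Y"` and `"n"` as in [AgeOutcomeTable].
#'
#' @exportClass JointAgeOutcomeTable
setClass("JointAgeOutcomeTable", contains = "SummarizedExperiment")

setValidity("JointAgeOutcomeTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (is.null(rd$mage) || is.null(rd$page)) {
    return("rowData must carry 'mage' and 'page'")
  }
  grid <- expand.grid(page = .PATERNAL_SPAN, mage = .MATERNAL_SPAN)
  if (nrow(object) != nrow(grid) ||
      !identical(as.integer(rd$mage), as.integer(grid$mage)) ||
      !identical(as.integer(rd$page), as.integer(grid$page))) {
    return("rows must enumerate the complete 35 x 51 age grid")
  }
  .validCounts(object)
})

#' @title TwoByTwoTable: exposure-by-outcome case counts
#'
#' @description For a binary exposure (Down syndrome or other chromosomal
#' disorder), the exposed and unexposed case and birth counts for each
#' outcome, as used by the beta-binomial odds-ratio model.
#'
#' @slot exposure `"ds"` or `"cd"`.
#' @slot counts `data.frame` with columns `outcome`, `casesExposed`,
#'   `birthsExposed`, `casesUnexposed`, `birthsUnexposed`.
#'
#' @exportClass TwoByTwoTable
setClass("TwoByTwoTable",
  representation(exposure = "character", counts = "data.frame")
)

setValidity("TwoByTwoTable", function(object) {
  if (!object@exposure %in% c("ds", "cd")) return("exposure must be 'ds' or 'cd'")
  ct <- object@counts
  need <- c("outcome", "casesExposed", "birthsExposed", "casesUnexposed",
            "birthsUnexposed")
  if (!all(need %in% names(ct))) {
    return(paste("counts needs columns:", paste(need, collapse = ", ")))
  }
  if (any(ct$casesExposed > ct$birthsExposed) ||
      any(ct$casesUnexposed > ct$birthsUnexposed)) {
    return("cases must not exceed births in either arm")
  }
  TRUE
})

#' @title ModelSpec: structure of a parental-age risk model
#'
#' @description Which age axes enter the linear predictor, their spans, and
#' the prior hyperparameters. The likelihood is binomial with a logit link;
#' each axis has a first-order random-walk (intrinsic CAR) prior over its age
#' effects with a Uniform(0, `sdUpper`) hyperprior on the random-walk
#' standard deviation, and the intercept has a flat improper prior. Setting
#' `sdFixed` for an axis replaces the hyperprior with a point mass (used for
#' validation against quadrature).
#'
#' @slot axes Character vector, subset of `c("maternal", "paternal")`.
#' @slot spans Named list of contiguous integer age vectors, one per axis.
#' @slot sdUpper Upper bound of the uniform hyperprior on each random-walk
#'   standard deviation (default 10).
#' @slot sdFixed Named numeric; `NA` per axis means the SD is sampled.
#'
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(
    axes = "character",
    spans = "list",
    sdUpper = "numeric",
    sdFixed = "numeric"
  )
)

setValidity("ModelSpec", function(object) {
  if (length(object@axes) == 0 ||
      !all(object@axes %in% c("maternal", "paternal"))) {
    return("axes must be a non-empty subset of maternal/paternal")
  }
  if (!setequal(names(object@spans), object@axes)) {
    return("spans must be named by the axes")
  }
  for (ax in object@axes) {
    sp <- object@spans[[ax]]
    if (length(sp) < 1 || !all(diff(sp) == 1)) {
      return("each span must be a contiguous integer age range")
    }
  }
  if (object@sdUpper <= 0) return("sdUpper must be positive")
  TRUE
})

#' @title MCMCConfig: sampler run configuration
#'
#' @description Chain count, burn-in, kept iterations, thinning interval,
#' seed, and proposal-adaptation settings for [samplePosterior()]. Defaults
#' mirror the long production protocol (2 chains, 5,000 burn-in iterations,
#' 200,000 further iterations thinned by 100, so 2,000 stored draws per
#' chain); tests and examples use much shorter chains.
#'
#' @slot nChains Number of independent chains (>= 1; >= 2 for diagnostics).
#' @slot burnIn Burn-in iterations, discarded; proposal scales adapt only
#'   here.
#' @slot iterations Post-burn-in iterations; must be divisible by `thin`.
#' @slot thin Keep every `thin`-th post-burn-in iteration.
#' @slot seed Integer seed; the run is fully reproducible from it.
#' @slot adaptDuringBurnIn Adapt proposal scales during burn-in.
#' @slot targetAcceptance Target acceptance rate for single-site updates.
#'
#' @exportClass MCMCConfig
setClass("MCMCConfig",
  representation(
    nChains = "integer",
    burnIn = "integer",
    iterations = "integer",
    thin = "integer",
    seed = "integer",
    adaptDuringBurnIn = "logical",
    targetAcceptance = "numeric"
  )
)

setValidity("MCMCConfig", function(object) {
  if (object@nChains < 1) return("nChains must be >= 1")
  if (object@burnIn < 0) return("burnIn must be >= 0")
  if (object@iterations < 1) return("iterations must be >= 1")
  if (object@thin < 1 || object@iterations %% object@thin != 0) {
    return("iterations must be divisible by thin")
  }
  if (object@targetAcceptance <= 0 || object@targetAcceptance >= 1) {
    return("targetAcceptance must lie in (0,1)")
  }
  TRUE
})

#' @title PosteriorDraws: thinned multi-chain MCMC output
#'
#' @description Stored draws for one outcome's model. Each chain contributes
#' a matrix with one row per stored draw and named columns: `alpha`, the
#' per-age effects (`maternal_15`, ..., `paternal_65`), and the random-walk
#' SDs (`sd_maternal`, `sd_paternal`). Effect vectors are recentred to sum
#' to zero within each axis at every stored draw.
#'
#' @slot chains List of draw matrices, one per chain.
#' @slot modelSpec The [ModelSpec] fitted.
#' @slot mcmcConfig The [MCMCConfig] used.
#' @slot outcome Outcome name the draws belong to.
#' @slot acceptance Named numeric vector of post-burn-in acceptance rates per
#'   parameter block, averaged over chains.
#'
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
  representation(
    chains = "list",
    modelSpec = "ModelSpec",
    mcmcConfig = "MCMCConfig",
    outcome = "character",
    acceptance = "numeric"
  )
)

setValidity("PosteriorDraws", function(object) {
  if (length(object@chains) < 1) return("at least one chain required")
  cn <- colnames(object@chains[[1]])
  for (ch in object@chains) {
    if (!identical(colnames(ch), cn)) return("chains must share parameter names")
  }
  TRUE
})

#' @title ConvergenceReport: split-Rhat and effective sample sizes
#'
#' @description Per-parameter split-Rhat statistics and effective sample
#' sizes computed from two or more chains, plus an overall converged flag.
#'
#' @slot stats `data.frame` with columns `parameter`, `rhat`, `ess`.
#' @slot threshold Rhat threshold used for the flag.
#' @slot converged `TRUE` if the maximum Rhat is below `threshold`.
#'
#' @exportClass ConvergenceReport
setClass("ConvergenceReport",
  representation(stats = "data.frame", threshold = "numeric",
                 converged = "logical")
)

#' @title ORCurve: per-age odds ratios standardized to a reference age
#'
#' @description Posterior summaries of the odds ratio at each age relative
#' to a reference age, computed draw-wise as `exp(effect_a - effect_ref)`.
#' At the reference age the odds ratio is exactly 1 with a zero-width
#' interval. The significance probability is the two-sided posterior tail
#' probability that the odds ratio differs from 1.
#'
#' @slot axis `"maternal"` or `"paternal"`.
#' @slot referenceAge Reference age in years.
#' @slot source `"total"` or `"adjusted"` (or `"truth"`, `"independent"`).
#' @slot table `data.frame` with columns `age`, `or`, `lo`, `hi`, `sig`.
#'
#' @exportClass ORCurve
setClass("ORCurve",
  representation(axis = "character", referenceAge = "integer",
                 source = "character", table = "data.frame")
)

setValidity("ORCurve", function(object) {
  tb <- object@table
  if (!all(c("age", "or", "lo", "hi", "sig") %in% names(tb))) {
    return("table needs columns age, or, lo, hi, sig")
  }
  if (any(tb$or <= 0) || any(tb$lo <= 0) || any(tb$hi <= 0)) {
    return("odds ratios must be positive")
  }
  iref <- match(object@referenceAge, tb$age)
  if (is.na(iref)) return("reference age must appear in the table")
  if (abs(tb$or[iref] - 1) > 1e-12 || tb$hi[iref] - tb$lo[iref] > 1e-12) {
    return("odds ratio at the reference age must be exactly 1 with zero width")
  }
  TRUE
})

#' @title ShapeClassification: U/J/monotone/flat label for a risk curve
#'
#' @description The label assigned to a posterior odds-ratio curve along one
#' age axis, with the evidence behind it: the trough (posterior-median
#' minimum-risk) age and the three pairwise comparisons youngest-vs-trough,
#' oldest-vs-trough and oldest-vs-youngest, each recorded as the posterior
#' median ratio, the two-sided tail probability, and whether the first age
#' is significantly higher-risk than the second.
#'
#' @slot axis `"maternal"` or `"paternal"`.
#' @slot label One of `"U"`, `"J"`, `"increasing"`, `"decreasing"`, `"flat"`.
#' @slot troughAge Age with the minimum posterior-median odds ratio.
#' @slot evidence `data.frame` with columns `comparison`, `medianRatio`,
#'   `pTwoSided`, `significantlyHigher`.
#' @slot anySignificant `TRUE` if any age differs significantly from the
#'   youngest (reference) age.
#'
#' @exportClass ShapeClassification
setClass("ShapeClassification",
  representation(axis = "character", label = "character",
                 troughAge = "integer", evidence = "data.frame",
                 anySignificant = "logical")
)

setValidity("ShapeClassification", function(object) {
  if (!object@label %in% c("U", "J", "increasing", "decreasing", "flat")) {
    return("label must be one of U, J, increasing, decreasing, flat")
  }
  TRUE
})

#' @title SimConfig: synthetic birth-cohort generator configuration
#'
#' @description All parameters of [simulateCohort()]: cohort size, the
#' maternal age distribution (rounded truncated normal), the paternal age
#' gap distribution, paternal-age missingness (elevated at young maternal
#' ages), logistic-in-maternal-age Down-syndrome and chromosomal-disorder
#' risks, and per-outcome baseline risks, parental log-odds-ratio age
#' curves, DS/CD odds multipliers and outcome missingness. See
#' [simConfig()] for construction and defaults.
#'
#' @slot nBirths Number of births to simulate.
#' @slot maternal List: `mean`, `sd`, `span` (integer range the rounded
#'   normal is truncated to).
#' @slot paternalGap List: `mean`, `sd`, `span` (range paternal age is
#'   truncated to after adding the gap).
#' @slot paternalMissing List: `base` probability, `young` probability, and
#'   maternal-age `cutoff` below which the young probability applies.
#' @slot dsRisk,cdRisk Lists: `baseline` probability at `refAge`, and
#'   per-year log-odds `slope` applied above `knot`.
#' @slot outcomes Named list (names from [nmmOutcomes()]); each element has
#'   `baseline`, `maternalCurve`, `paternalCurve` (see [ageCurve()]),
#'   `orDS`, `orCD`, `missing`.
#' @slot seed Integer seed.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nBirths = "integer",
    maternal = "list",
    paternalGap = "list",
    paternalMissing = "list",
    dsRisk = "list",
    cdRisk = "list",
    outcomes = "list",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  if (object@nBirths < 1) return("nBirths must be >= 1")
  if (!all(names(object@outcomes) %in% nmmOutcomes())) {
    return("outcome names must come from nmmOutcomes()")
  }
  for (nm in names(object@outcomes)) {
    oc <- object@outcomes[[nm]]
    if (oc$baseline < 0 || oc$baseline > 1) return("baselines must be in [0,1]")
    if (oc$missing < 0 || oc$missing > 1) return("missingness must be in [0,1]")
    if (oc$orDS <= 0 || oc$orCD <= 0) return("DS/CD odds ratios must be positive")
  }
  pm <- object@paternalMissing
  if (any(unlist(pm[c("base", "young")]) < 0) ||
      any(unlist(pm[c("base", "young")]) > 1)) {
    return("missingness probabilities must be in [0,1]")
  }
  TRUE
})
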