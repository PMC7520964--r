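## Seeded synthetic birth-cohort generator. It emulates the statistical
## structure the models assume -- correlated parent ages, paternal-age
## missingness concentrated at young maternal ages, maternal-age-dependent
## DS/CD risk, outcome risks nonlinear in both parents' ages with DS/CD as
## strong odds multipliers -- and records exact ground truth for recovery
## experiments.

#' Quadratic log-odds-ratio age curve about a trough
#'
#' `f(age) = young * (trough - age)^2` below the trough and
#' `old * (age - trough)^2` above it, with `f(trough) = 0`. Equal
#' coefficients give a symmetric U; a larger `old` gives a J; `young = 0`
#' gives a risk increasing with age; both zero give a flat curve.
#'
#' @param trough Minimum-risk age in years.
#' @param young,old Log-odds-ratio per squared year on each side.
#' @return A curve specification for [simConfig()].
#' @export
#' @examples
#' evalAgeCurve(ageCurve(30, young = 0.002, old = 0.003), c(15, 30, 49))
ageCurve <- function(trough, young, old = young) {
  list(type = "quadratic", trough = trough, young = young, old = old)
}

#' Tabulated log-odds-ratio age curve
#'
#' An explicit per-age table of log odds ratios; ages outside the table
#' are clamped to the nearest tabulated age.
#'
#' @param ages Integer ages.
#' @param values Log odds ratios at those ages.
#' @return A curve specification for [simConfig()].
#' @export
ageCurveTable <- function(ages, values) {
  stopifnot(length(ages) == length(values), !is.unsorted(ages))
  list(type = "table", ages = as.integer(ages), values = as.numeric(values))
}

#' Evaluate a log-odds-ratio age curve
#'
#' @param curve A curve from [ageCurve()] or [ageCurveTable()].
#' @param ages Ages to evaluate at.
#' @return Numeric vector of log odds ratios; all values finite.
#' @export
evalAgeCurve <- function(curve, ages) {
  out <- switch(curve$type,
    quadratic = ifelse(ages < curve$trough,
                       curve$young * (curve$trough - ages)^2,
                       curve$old * (ages - curve$trough)^2),
    table = curve$values[pmin(pmax(findInterval(ages, curve$ages), 1),
                              length(curve$ages))],
    stop("unknown curve type: ", curve$type)
  )
  if (any(!is.finite(out))) stop("curve evaluates to non-finite values")
  out
}

#' Per-outcome simulation settings
#'
#' @param baseline Outcome probability at the zero point of both age
#'   curves for a DS/CD-negative birth.
#' @param maternalCurve,paternalCurve Log-odds-ratio age curves
#'   ([ageCurve()] / [ageCurveTable()]); `NULL` means no age effect.
#' @param orDS,orCD Odds multipliers for Down syndrome and other
#'   chromosomal disorders.
#' @param missing Probability the outcome value is missing on the record.
#' @return A list for the `outcomes` slot of [simConfig()].
#' @export
outcomeSpec <- function(baseline, maternalCurve = NULL,
                        paternalCurve = NULL, orDS = 1, orCD = 1,
                        missing = 0) {
  flat <- ageCurve(30, 0, 0)
  list(baseline = baseline,
       maternalCurve = if (is.null(maternalCurve)) flat else maternalCurve,
       paternalCurve = if (is.null(paternalCurve)) flat else paternalCurve,
       orDS = orDS, orCD = orCD, missing = missing)
}

#' Default per-outcome simulation settings
#'
#' Baseline risks near published US rates, risk troughs at maternal age 30
#' and paternal age 35, J-shaped or U-shaped age curves of moderate size,
#' and DS/CD odds multipliers of the magnitude seen in national data.
#'
#' @return Named list of [outcomeSpec()]s for all ten outcomes.
#' @export
defaultOutcomeSpecs <- function() {
  m <- function(young, old) ageCurve(30, young / 225, old / 361)
  p <- function(young, old) ageCurve(35, young / 400, old / 900)
  ## helper arguments are the log-OR reached at the span ends
  list(
    preterm = outcomeSpec(0.075, m(0.20, 0.80), p(0.27, 0.26),
                          orDS = 4.2, orCD = 6.0, missing = 0.001),
    very_preterm = outcomeSpec(0.012, m(0.39, 0.69), p(0.37, 0.33),
                               orDS = 2.8, orCD = 8.1, missing = 0.001),
    sga = outcomeSpec(0.095, m(0.47, -0.04), p(0.12, 0.38),
                      orDS = 2.3, orCD = 5.2, missing = 0.001),
    low_apgar = outcomeSpec(0.004, m(0.34, 0.28), p(0.35, 0.32),
                            orDS = 4.7, orCD = 31.4, missing = 0.001),
    nicu = outcomeSpec(0.075, m(0.11, 0.59), p(0.17, 0.29),
                       orDS = 15.7, orCD = 15.9, missing = 0.001),
    antibiotics = outcomeSpec(0.018, m(0.22, 0.20), p(0.11, 0.16),
                              orDS = 7.8, orCD = 11.4, missing = 0.001),
    surfactant = outcomeSpec(0.005, m(0.21, 0.51), p(0.16, 0.13),
                             orDS = 6.0, orCD = 16.4, missing = 0.001),
    prolonged_ventilation = outcomeSpec(0.005, m(0.06, 0.57), p(0.18, 0.12),
                                        orDS = 12.7, orCD = 22.9,
                                        missing = 0.001),
    seizures = outcomeSpec(0.0004, m(0.02, 0.02), p(0.02, 0.02),
                           orDS = 11.7, orCD = 49.7, missing = 0.001),
    death = outcomeSpec(0.002, m(0.34, 0.58), p(0.16, 0.15),
                        orDS = 12.6, orCD = 70.2, missing = 0.001)
  )
}

#' Construct a SimConfig
#'
#' Defaults describe a cohort resembling recent US national natality data:
#' maternal ages from a rounded normal (mean 29, SD 6) truncated to 13-52;
#' paternal age = maternal age + a rounded normal gap (mean 2.5, SD 4),
#' truncated to 13-70; paternal age missing with probability 0.10,
#' rising to 0.60 when the mother is under 18; Down-syndrome risk 1/1000
#' below maternal age 30 with log odds rising 0.18/year above it; other
#' chromosomal disorders 1/2000 with slope 0.12/year; outcome settings
#' from [defaultOutcomeSpecs()].
#'
#' @param nBirths Number of births.
#' @param maternal List `mean`, `sd`, `span` for the maternal age
#'   distribution.
#' @param paternalGap List `mean`, `sd`, `span` (span truncates the
#'   resulting paternal age).
#' @param paternalMissing List `base`, `young`, `cutoff`.
#' @param dsRisk,cdRisk Lists `baseline`, `knot`, `slope`.
#' @param outcomes Named list of [outcomeSpec()]s (names from
#'   [nmmOutcomes()]); unlisted outcomes are emitted as all-`FALSE`.
#' @param anthropometrics Logical; also simulate gestational length and a
#'   gestation-dependent birthweight (for SGA-derivation testing).
#' @param seed Integer seed.
#' @return A [SimConfig].
#' @export
simConfig <- function(nBirths,
                      maternal = list(mean = 29, sd = 6, span = c(13, 52)),
                      paternalGap = list(mean = 2.5, sd = 4, span = c(13, 70)),
                      paternalMissing = list(base = 0.10, young = 0.60,
                                             cutoff = 18),
                      dsRisk = list(baseline = 0.001, knot = 30, slope = 0.18),
                      cdRisk = list(baseline = 0.0005, knot = 30, slope = 0.12),
                      outcomes = defaultOutcomeSpecs(),
                      anthropometrics = FALSE,
                      seed = 1L) {
  cfg <- new("SimConfig",
    nBirths = as.integer(nBirths), maternal = maternal,
    paternalGap = paternalGap, paternalMissing = paternalMissing,
    dsRisk = dsRisk, cdRisk = cdRisk, outcomes = outcomes,
    seed = as.integer(seed)
  )
  attr(cfg, "anthropometrics") <- anthropometrics
  cfg
}

.roundedTruncNorm <- function(n, mean, sd, span) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < span[1] | x > span[2])
  while (length(bad) > 0) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < span[1] | x[bad] > span[2]]
  }
  as.integer(x)
}

#' Simulate a birth cohort with known ground truth
#'
#' Draws each birth's maternal age from a rounded truncated normal, the
#' paternal age as maternal age plus a rounded gap (re-drawn until the
#' paternal age lies in its span), then masks the paternal age by the
#' missingness rule. DS and CD are Bernoulli with logistic-in-maternal-age
#' risks. Each configured outcome is Bernoulli with
#' `logit(p) = logit(baseline) + f_m(mage) + f_p(page) + log(orDS) ds +
#' log(orCD) cd`; when the paternal age is missing, `f_p` is evaluated at
#' the maternal age plus the mean gap (rounded) -- those records are
#' deleted by the study filter anyway. Very-preterm births are forced to
#' also be preterm. Outcome missingness is applied last. Fully
#' reproducible from the seed.
#'
#' @param config A [SimConfig].
#' @return List with `cohort` (a [BirthCohort]) and `truth` (a list:
#'   `orDS`, `orCD`, per-outcome true odds multipliers; `curves`, the
#'   configured age curves; `planted`, named counts of violations the
#'   study filter should find, using the filter's own precedence rules).
#' @export
simulateCohort <- function(config) {
  set.seed(config@seed)
  n <- config@nBirths
  mat <- config@maternal
  gap <- config@paternalGap

  mage <- .roundedTruncNorm(n, mat$mean, mat$sd, mat$span)
  g <- round(rnorm(n, gap$mean, gap$sd))
  page <- mage + g
  bad <- which(page < gap$span[1] | page > gap$span[2])
  while (length(bad) > 0) {
    page[bad] <- mage[bad] + round(rnorm(length(bad), gap$mean, gap$sd))
    bad <- bad[page[bad] < gap$span[1] | page[bad] > gap$span[2]]
  }
  page <- as.integer(page)

  pm <- config@paternalMissing
  pMiss <- ifelse(mage < pm$cutoff, pm$young, pm$base)
  page[runif(n) < pMiss] <- NA_integer_

  riskProb <- function(risk) {
    plogis(qlogis(risk$baseline) + risk$slope * pmax(0, mage - risk$knot))
  }
  ds <- runif(n) < riskProb(config@dsRisk)
  cd <- runif(n) < riskProb(config@cdRisk)

  ## paternal-age stand-in where the father is missing (filtered out later)
  pageEff <- ifelse(is.na(page), mage + round(gap$mean), page)

  rec <- data.frame(mage = mage, page = page)
  rec$ds <- ds
  rec$cd <- cd
  for (oc in nmmOutcomes()) rec[[oc]] <- rep(FALSE, n)
  for (oc in names(config@outcomes)) {
    sp <- config@outcomes[[oc]]
    eta <- qlogis(sp$baseline) +
      evalAgeCurve(sp$maternalCurve, mage) +
      evalAgeCurve(sp$paternalCurve, pageEff) +
      log(sp$orDS) * ds + log(sp$orCD) * cd
    rec[[oc]] <- runif(n) < plogis(eta)
  }
  if (all(c("preterm", "very_preterm") %in% names(config@outcomes))) {
    rec$preterm <- rec$preterm | rec$very_preterm
  }
  for (oc in names(config@outcomes)) {
    pm_oc <- config@outcomes[[oc]]$missing
    if (pm_oc > 0) rec[[oc]][runif(n) < pm_oc] <- NA
  }

  if (isTRUE(attr(config, "anthropometrics"))) {
    gd <- pmin(pmax(round(rnorm(n, 273, 12)), 200), 310)
    gd[rec$very_preterm %in% TRUE] <- pmin(gd[rec$very_preterm %in% TRUE], 223)
    wt <- round(3400 + 20 * (gd - 273) + rnorm(n, 0, 420))
    rec$birthweight_g <- as.integer(pmax(wt, 250))
    rec$gestation_days <- as.integer(gd)
  }

  cohort <- birthCohort(rec, provenance = sprintf("simulated (seed %d)",
                                                  config@seed))

  ## planted violation counts with the filter's precedence
  motherUnder <- mage < 15L
  motherOver <- mage > 49L
  motherOk <- !motherUnder & !motherOver
  fatherBad <- motherOk & (is.na(page) | page < 15L | page > 65L)
  parentOk <- motherOk & !fatherBad
  anyMissing <- Reduce(`|`, lapply(nmmOutcomes(),
                                   function(oc) is.na(rec[[oc]])))
  outcomeMissing <- parentOk & anyMissing
  planted <- c(
    nMotherUnderMin = sum(motherUnder),
    nMotherOverMax = sum(motherOver),
    nFatherOutOfRangeOrMissing = sum(fatherBad),
    nDeletedForMissingOutcome = sum(outcomeMissing),
    nRetained = sum(parentOk & !anyMissing)
  )

  truth <- list(
    orDS = vapply(config@outcomes, function(sp) sp$orDS, numeric(1)),
    orCD = vapply(config@outcomes, function(sp) sp$orCD, numeric(1)),
    curves = lapply(config@outcomes, function(sp) {
      list(maternal = sp$maternalCurve, paternal = sp$paternalCurve)
    }),
    planted = planted
  )
  list(cohort = cohort, truth = truth)
}

#' Ground-truth odds-ratio curve of a simulation configuration
#'
#' Evaluates `exp(f(age) - f(referenceAge))` from the configured log-OR
#' curve over the study span of the axis.
#'
#' @param config A [SimConfig].
#' @param outcome Outcome name (must be configured).
#' @param axis `"maternal"` or `"paternal"`.
#' @param referenceAge Reference age (default 15).
#' @return An [ORCurve] with zero-width intervals and
#'   `source = "truth"`.
#' @export
trueORCurve <- function(config, outcome, axis = c("maternal", "paternal"),
                        referenceAge = 15L) {
  axis <- match.arg(axis)
  if (!outcome %in% names(config@outcomes)) {
    stop("outcome ", outcome, " is not configured")
  }
  curve <- config@outcomes[[outcome]][[paste0(
    if (axis == "maternal") "maternal" else "paternal", "Curve")]]
  ages <- .axisSpan(axis)
  f <- evalAgeCurve(curve, ages)
  fr <- evalAgeCurve(curve, referenceAge)
  or <- exp(f - fr)
  tab <- data.frame(age = ages, or = or, lo = or, hi = or,
                    sig = as.numeric(or == 1))
  iref <- match(referenceAge, ages)
  tab$or[iref] <- 1; tab$lo[iref] <- 1; tab$hi[iref] <- 1; tab$sig[iref] <- 1
  new("ORCurve", axis = axis, referenceAge = as.integer(referenceAge),
      source = "truth", table = tab)
}
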