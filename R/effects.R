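## Posterior summaries in the study's reporting currency: beta-binomial
## odds ratios for DS/CD exposure, age-OR curves standardized to a
## reference age, pairwise ORs between ages, U/J-shape classification, and
## the four model presets (total/adjusted x maternal/paternal).

#' Posterior draws of one axis's age effects
#'
#' @param draws A [PosteriorDraws].
#' @param axis `"maternal"` or `"paternal"`.
#' @return Matrix (pooled draws x ages); column names are the ages.
#' @export
effectDraws <- function(draws, axis = c("maternal", "paternal")) {
  axis <- match.arg(axis)
  if (!axis %in% draws@modelSpec@axes) {
    stop("draws do not contain the ", axis, " axis")
  }
  span <- draws@modelSpec@spans[[axis]]
  dm <- drawMatrix(draws)
  e <- dm[, paste0(axis, "_", span), drop = FALSE]
  colnames(e) <- span
  e
}

.twoSidedP <- function(x, refValue = 1) {
  ## two-sided posterior tail probability that x differs from refValue;
  ## >= / <= so that degenerate all-equal draws give p = 1, not 0
  min(1, 2 * min(mean(x >= refValue), mean(x <= refValue)))
}

#' Beta-binomial odds ratios for a binary exposure
#'
#' For each outcome, draws the exposed and unexposed event rates from
#' their exact posteriors under a Uniform(0,1) prior -- `Beta(Y+1, n-Y+1)`
#' in each arm -- forms the odds-ratio draws
#' `[mu2/(1-mu2)] / [mu1/(1-mu1)]`, and reports the posterior median and
#' central 95% credible interval.
#'
#' @param table A [TwoByTwoTable].
#' @param nDraws Monte-Carlo draws per arm (default 100,000).
#' @param seed Integer seed.
#' @return `data.frame` with columns `outcome`, `exposure`, `or`, `lo`,
#'   `hi`, `nDraws`.
#' @export
estimateBinaryOR <- function(table, nDraws = 100000L, seed = 1L) {
  ct <- table@counts
  if (any(ct$birthsExposed == 0) || any(ct$birthsUnexposed == 0)) {
    stop("odds ratio undefined: an arm has zero births")
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(ct)), function(k) {
    mu2 <- rbeta(nDraws, ct$casesExposed[k] + 1,
                 ct$birthsExposed[k] - ct$casesExposed[k] + 1)
    mu1 <- rbeta(nDraws, ct$casesUnexposed[k] + 1,
                 ct$birthsUnexposed[k] - ct$casesUnexposed[k] + 1)
    or <- (mu2 / (1 - mu2)) / (mu1 / (1 - mu1))
    q <- quantile(or, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(outcome = ct$outcome[k], exposure = table@exposure,
               or = q[1], lo = q[2], hi = q[3], nDraws = nDraws)
  }))
  out
}

#' Format an odds ratio with its 95% credible interval
#'
#' @param or,lo,hi Numeric scalars or vectors.
#' @param digits Significant digits.
#' @return Character vector like `"12.6 (11.1, 14.3)"`.
#' @export
formatOR <- function(or, lo, hi, digits = 3) {
  sprintf("%s (%s, %s)", signif(or, digits), signif(lo, digits),
          signif(hi, digits))
}

#' Odds-ratio curve standardized to a reference age
#'
#' For every age `a` on the axis, forms the draw-wise odds ratio
#' `exp(effect_a - effect_ref)` and summarizes it by the posterior median,
#' the central 95% credible interval, and the two-sided posterior tail
#' probability that the odds ratio differs from 1. The reference age maps
#' to an odds ratio of exactly 1 with a zero-width interval.
#'
#' @param draws A [PosteriorDraws].
#' @param axis `"maternal"` or `"paternal"`.
#' @param referenceAge Reference age in years (default 15, the youngest
#'   study age).
#' @param source Label stored on the curve (`"total"` or `"adjusted"`).
#' @return An [ORCurve].
#' @export
orCurve <- function(draws, axis = c("maternal", "paternal"),
                    referenceAge = 15L, source = "total") {
  axis <- match.arg(axis)
  e <- effectDraws(draws, axis)
  ages <- as.integer(colnames(e))
  if (!referenceAge %in% ages) {
    stop("reference age ", referenceAge, " is outside the ", axis, " span")
  }
  logOR <- e - e[, as.character(referenceAge)]
  tab <- data.frame(
    age = ages,
    or = exp(apply(logOR, 2, median)),
    lo = exp(apply(logOR, 2, quantile, 0.025, names = FALSE)),
    hi = exp(apply(logOR, 2, quantile, 0.975, names = FALSE)),
    sig = apply(exp(logOR), 2, .twoSidedP)
  )
  iref <- match(referenceAge, ages)
  tab$or[iref] <- 1; tab$lo[iref] <- 1; tab$hi[iref] <- 1; tab$sig[iref] <- 1
  rownames(tab) <- NULL
  new("ORCurve", axis = axis, referenceAge = as.integer(referenceAge),
      source = source, table = tab)
}

#' Pairwise odds ratio between two ages
#'
#' Summarizes `exp(effect_a - effect_b)` across draws: the odds of the
#' outcome at age `ageA` relative to age `ageB`, with posterior median,
#' 95% credible interval and two-sided significance probability. This is
#' the quantity used to compare the extreme ages with the minimum-risk age
#' (maternal 30, paternal 35).
#'
#' @param draws A [PosteriorDraws].
#' @param axis `"maternal"` or `"paternal"`.
#' @param ageA,ageB Ages within the axis span.
#' @return One-row `data.frame`: `axis`, `ageA`, `ageB`, `or`, `lo`, `hi`,
#'   `sig`, `nDraws`.
#' @export
pairwiseOR <- function(draws, axis = c("maternal", "paternal"), ageA, ageB) {
  axis <- match.arg(axis)
  e <- effectDraws(draws, axis)
  for (a in c(ageA, ageB)) {
    if (!as.character(a) %in% colnames(e)) {
      stop("age ", a, " is outside the ", axis, " span")
    }
  }
  r <- exp(e[, as.character(ageA)] - e[, as.character(ageB)])
  data.frame(
    axis = axis, ageA = ageA, ageB = ageB,
    or = median(r),
    lo = quantile(r, 0.025, names = FALSE),
    hi = quantile(r, 0.975, names = FALSE),
    sig = .twoSidedP(r),
    nDraws = length(r)
  )
}

#' Classify a posterior risk curve as U, J, monotone or flat
#'
#' The trough is the age with the minimum posterior-median odds ratio
#' (ties broken toward the youngest age). Age `a` is "significantly
#' higher" than age `b` when the two-sided posterior tail probability of
#' their odds ratio is below 0.05 and the posterior median ratio exceeds
#' 1. With `S(a,b)` denoting that relation, and comparing the youngest
#' age, the oldest age and the trough:
#' * `J`: both ends significantly above the trough and the oldest
#'   significantly above the youngest;
#' * `U`: both ends significantly above the trough but the two ends not
#'   significantly different;
#' * `increasing`: only the old end above the trough;
#' * `decreasing`: only the young end above the trough;
#' * `flat`: neither.
#'
#' The report also records whether any age differs significantly from the
#' youngest (reference) age -- the curve-level significance criterion.
#'
#' @param draws A [PosteriorDraws].
#' @param axis `"maternal"` or `"paternal"`.
#' @param sigLevel Two-sided significance threshold (default 0.05).
#' @return A [ShapeClassification].
#' @export
classifyShape <- function(draws, axis = c("maternal", "paternal"),
                          sigLevel = 0.05) {
  axis <- match.arg(axis)
  e <- effectDraws(draws, axis)
  ages <- as.integer(colnames(e))
  if (length(ages) < 3) stop("shape classification needs at least 3 ages")
  med <- apply(e, 2, median)
  trough <- ages[which.min(med)]
  youngest <- ages[1]
  oldest <- ages[length(ages)]

  compare <- function(a, b) {
    r <- exp(e[, as.character(a)] - e[, as.character(b)])
    p <- .twoSidedP(r)
    data.frame(medianRatio = median(r), pTwoSided = p,
               significantlyHigher = p < sigLevel && median(r) > 1)
  }
  yt <- compare(youngest, trough)
  ot <- compare(oldest, trough)
  oy <- compare(oldest, youngest)
  evidence <- cbind(
    data.frame(comparison = c("youngest_vs_trough", "oldest_vs_trough",
                              "oldest_vs_youngest")),
    rbind(yt, ot, oy)
  )
  label <-
    if (yt$significantlyHigher && ot$significantlyHigher) {
      if (oy$significantlyHigher) "J" else "U"
    } else if (ot$significantlyHigher) {
      "increasing"
    } else if (yt$significantlyHigher) {
      "decreasing"
    } else {
      "flat"
    }
  logOR <- e - e[, 1]
  perAgeP <- apply(exp(logOR[, -1, drop = FALSE]), 2, .twoSidedP)
  new("ShapeClassification", axis = axis, label = label,
      troughAge = as.integer(trough), evidence = evidence,
      anySignificant = any(perAgeP < sigLevel))
}

#' Independent per-age beta-binomial odds-ratio curve
#'
#' The no-smoothing comparator to the random-walk model: each age's event
#' rate gets an independent `Beta(Y+1, n-Y+1)` posterior (Uniform prior),
#' and the per-age odds-ratio draws against the reference age are
#' summarized exactly as in [orCurve()]. Used to quantify the precision
#' gained by autoregressive smoothing.
#'
#' @param table An [AgeOutcomeTable].
#' @param outcome Outcome name.
#' @param referenceAge Reference age (default 15).
#' @param nDraws Draws per age (default 4,000).
#' @param seed Integer seed.
#' @return An [ORCurve] with `source = "independent"`. Ages with `n = 0`
#'   get maximally diffuse Beta(1,1) posteriors.
#' @export
independentBetaCurve <- function(table, outcome, referenceAge = 15L,
                                 nDraws = 4000L, seed = 1L) {
  oc <- outcomeCounts(table, outcome)
  ages <- as.integer(oc$rowData$age)
  set.seed(seed)
  mu <- vapply(seq_along(ages), function(i) {
    rbeta(nDraws, oc$Y[i] + 1, oc$n[i] - oc$Y[i] + 1)
  }, numeric(nDraws))
  odds <- mu / (1 - mu)
  iref <- match(referenceAge, ages)
  if (is.na(iref)) stop("reference age outside the table span")
  or <- odds / odds[, iref]
  tab <- data.frame(
    age = ages,
    or = apply(or, 2, median),
    lo = apply(or, 2, quantile, 0.025, names = FALSE),
    hi = apply(or, 2, quantile, 0.975, names = FALSE),
    sig = apply(or, 2, .twoSidedP)
  )
  tab$or[iref] <- 1; tab$lo[iref] <- 1; tab$hi[iref] <- 1; tab$sig[iref] <- 1
  new("ORCurve", axis = table@axis, referenceAge = as.integer(referenceAge),
      source = "independent", table = tab)
}

#' Fit one of the four study model presets
#'
#' * `total_maternal` / `total_paternal`: univariate model on the full
#'   filtered cohort; the unadjusted (total) parental-age effect.
#' * `adjusted_maternal`: cohort restricted to births negative for both DS
#'   and CD, joint maternal + paternal model; the maternal curve is
#'   reported.
#' * `adjusted_paternal`: joint model on all filtered data (DS/CD births
#'   included); the paternal curve is reported.
#'
#' All curves are standardized to age 15.
#'
#' @param cohort A filtered [BirthCohort].
#' @param preset One of the four preset names.
#' @param outcomes Outcomes to fit (default all ten).
#' @param config An [MCMCConfig]; each outcome's seed is offset from it so
#'   outcome fits are independent but reproducible.
#' @param referenceAge Reference age for the reported curves.
#' @return Named list (one element per outcome) of lists with `curve`
#'   ([ORCurve]), `shape` ([ShapeClassification]), `draws`
#'   ([PosteriorDraws]) and `convergence` ([ConvergenceReport] or `NULL`
#'   when a single chain was run).
#' @export
runPreset <- function(cohort,
                      preset = c("total_maternal", "total_paternal",
                                 "adjusted_maternal", "adjusted_paternal"),
                      outcomes = nmmOutcomes(), config = mcmcConfig(),
                      referenceAge = 15L) {
  preset <- match.arg(preset)
  axis <- if (grepl("maternal", preset)) "maternal" else "paternal"
  adjusted <- grepl("adjusted", preset)
  source <- if (adjusted) "adjusted" else "total"
  dat <- cohort
  if (preset == "adjusted_maternal") {
    rec <- cohort@records
    keep <- !rec$ds & !rec$cd
    keep[is.na(keep)] <- FALSE
    dat <- new("BirthCohort", records = rec[keep, , drop = FALSE],
               provenance = paste0(cohort@provenance, " [DS/CD negative]"))
  }
  table <- if (adjusted) tabulateJoint(dat) else tabulateByAge(dat, axis)
  out <- lapply(setNames(outcomes, outcomes), function(oc) {
    k <- match(oc, nmmOutcomes())
    cfg <- mcmcConfig(config@nChains, config@burnIn, config@iterations,
                      config@thin, config@seed + k,
                      config@adaptDuringBurnIn, config@targetAcceptance)
    draws <- samplePosterior(table, outcome = oc, config = cfg)
    list(
      curve = orCurve(draws, axis, referenceAge, source = source),
      shape = classifyShape(draws, axis),
      draws = draws,
      convergence = if (cfg@nChains >= 2) computeRhat(draws) else NULL
    )
  })
  out
}

#' Plot an odds-ratio curve
#'
#' Posterior median odds ratio by age with a shaded 95% credible band, on
#' a log odds-ratio scale, with the reference line at 1.
#'
#' @param curve An [ORCurve] (further curves can be added with `add`).
#' @param add Logical; draw into an existing plot.
#' @param col Line/band colour.
#' @param main Plot title.
#' @return Invisibly, the curve's table.
#' @export
plotORCurve <- function(curve, add = FALSE, col = "steelblue",
                        main = NULL) {
  tb <- curve@table
  if (!add) {
    if (is.null(main)) {
      main <- sprintf("%s age odds ratio (ref %d, %s)", curve@axis,
                      curve@referenceAge, curve@source)
    }
    graphics::plot(tb$age, tb$or, type = "n", log = "y",
                   ylim = range(c(tb$lo, tb$hi)),
                   xlab = sprintf("%s age (years)", curve@axis),
                   ylab = "odds ratio", main = main)
    graphics::abline(h = 1, lty = 3)
  }
  shade <- grDevices::adjustcolor(col, alpha.f = 0.25)
  graphics::polygon(c(tb$age, rev(tb$age)), c(tb$lo, rev(tb$hi)),
                    border = NA, col = shade)
  graphics::lines(tb$age, tb$or, col = col, lwd = 2)
  invisible(tb)
}
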