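test_that("binary OR summaries behave on symmetric and extreme tables", {
  mk <- function(ce, be, cu, bu, exposure = "ds") {
    counts <- do.call(rbind, lapply(nmmOutcomes()[1], function(oc) {
      data.frame(outcome = oc, casesExposed = ce, birthsExposed = be,
                 casesUnexposed = cu, birthsUnexposed = bu)
    }))
    new("TwoByTwoTable", exposure = exposure, counts = counts)
  }
  sym <- estimateBinaryOR(mk(5, 50, 5, 50), seed = 2)
  expect_lt(abs(sym$or - 1), 0.15)
  expect_lt(sym$lo, 1)
  expect_gt(sym$hi, 1)

  strong <- estimateBinaryOR(mk(100, 1000, 10, 1000), nDraws = 200000L,
                             seed = 3)
  ## sample OR (100/900)/(10/990) = 11.0
  expect_lt(abs(strong$or - 11) / 11, 0.1)
  expect_gt(strong$lo, 1)

  expect_error(estimateBinaryOR(mk(0, 0, 5, 50)), "zero births")
  ## the reporting convention: "OR (lo, hi)"
  expect_match(formatOR(strong$or, strong$lo, strong$hi),
               "^[0-9.]+ \\([0-9.]+, [0-9.]+\\)$")
})

test_that("OR curve is exactly 1 at its reference age", {
  d <- curveDraws(means = c(0.5, 0.2, 0, 0.1, 0.4), se = 0.1)
  cv <- orCurve(d, "maternal", referenceAge = 15L)
  tb <- curveTable(cv)
  expect_identical(tb$or[tb$age == 15], 1)
  expect_identical(tb$hi[tb$age == 15] - tb$lo[tb$age == 15], 0)
  expect_identical(tb$sig[tb$age == 15], 1)
  expect_true(all(tb$lo <= tb$or & tb$or <= tb$hi))
  expect_error(orCurve(d, "maternal", referenceAge = 60L), "outside")
})

test_that("degenerate draws give closed-form ORs with zero-width intervals", {
  e <- matrix(rep(c(0, -0.2, 0.3), each = 50), nrow = 50)
  d <- syntheticDraws(e)
  tb <- curveTable(orCurve(d, "maternal", referenceAge = 15L))
  expect_equal(tb$or[tb$age == 16], exp(-0.2), tolerance = 1e-12)
  expect_equal(tb$lo[tb$age == 16], tb$hi[tb$age == 16])
  expect_equal(tb$sig[tb$age == 16], 0)  # all draws below 1
  expect_equal(tb$or[tb$age == 17], exp(0.3), tolerance = 1e-12)
})

test_that("re-referencing an OR curve is a draw-wise division", {
  d <- curveDraws(means = c(0.4, 0.1, 0, 0.2), se = 0.2, seed = 7)
  cv15 <- curveTable(orCurve(d, "maternal", referenceAge = 15L))
  cv17 <- curveTable(orCurve(d, "maternal", referenceAge = 17L))
  e <- effectDraws(d, "maternal")
  reref <- exp(e - e[, "17"])
  ## only to interpolation accuracy: the type-7 median interpolates between
  ## order statistics, and interpolation does not commute with exp()
  expect_equal(cv17$or[cv17$age != 17],
               unname(apply(reref, 2, median)[colnames(e) != "17"]),
               tolerance = 1e-6)
  ## medians transform consistently between references at the ages
  ## themselves (only approximately: type-7 quantile interpolation does
  ## not commute exactly with taking reciprocals)
  expect_equal(cv15$or[cv15$age == 17] * cv17$or[cv17$age == 15], 1,
               tolerance = 1e-6)
})

test_that("pairwise ORs are reciprocal and exact on equal ages", {
  d <- curveDraws(means = c(0.3, 0, 0.5), se = 0.15, seed = 11)
  same <- pairwiseOR(d, "maternal", 16, 16)
  expect_identical(same$or, 1)
  ab <- pairwiseOR(d, "maternal", 17, 15)
  ba <- pairwiseOR(d, "maternal", 15, 17)
  ## approximate reciprocity: quantile interpolation does not commute
  ## exactly with reciprocals
  expect_equal(ab$or * ba$or, 1, tolerance = 1e-6)
  expect_equal(ab$lo, 1 / ba$hi, tolerance = 1e-6)
  expect_equal(ab$hi, 1 / ba$lo, tolerance = 1e-6)
  expect_error(pairwiseOR(d, "maternal", 15, 99), "outside")
})

test_that("shape classification distinguishes the canonical patterns", {
  span <- 15:49
  quad <- function(young, old, trough = 30) {
    ## guard the scale denominators when the trough sits at a span end
    dy <- max((trough - 15)^2, 1)
    do <- max((49 - trough)^2, 1)
    ifelse(span < trough, young * (trough - span)^2 / dy,
           old * (span - trough)^2 / do)
  }
  classify <- function(means, se = 0.05, seed = 13) {
    shapeLabel(classifyShape(curveDraws(means, se, seed = seed), "maternal"))
  }
  expect_equal(classify(quad(0.5, 0.5)), "U")
  expect_equal(classify(quad(0.4, 0.8)), "J")
  expect_equal(classify(quad(0, 0.6, trough = 15)), "increasing")
  expect_equal(classify(quad(0.6, 0, trough = 49)), "decreasing")
  expect_equal(classify(rep(0, length(span)), se = 0.05), "flat")

  flat <- classifyShape(curveDraws(rep(0, 35), 0.05, seed = 15), "maternal")
  expect_false(flat@anySignificant)
  expect_error(classifyShape(curveDraws(c(0, 1), 0.1), "maternal"),
               "3 ages")
})

test_that("a J-shaped national preterm pattern classifies as J", {
  ## posterior pattern matching published maternal preterm summaries:
  ## young OR 1.22 (1.16, 1.30) and old OR 2.20 (2.00, 2.44) against an
  ## age-30 trough
  span <- 15:49
  nDraws <- 4000
  set.seed(20)
  youngLogOR <- rnorm(nDraws, log(1.22), (log(1.30) - log(1.16)) / 3.92)
  oldLogOR <- rnorm(nDraws, log(2.20), (log(2.44) - log(2.00)) / 3.92)
  e <- sapply(span, function(a) {
    if (a < 30) youngLogOR * ((30 - a) / 15)^2
    else oldLogOR * ((a - 30) / 19)^2
  })
  shape <- classifyShape(syntheticDraws(e), "maternal")
  expect_equal(shapeLabel(shape), "J")
  expect_equal(shape@troughAge, 30L)
  expect_true(shape@anySignificant)
})

test_that("independent per-age Beta curve is valid and wider than smoothed",
{
  sim <- simulateCohort(recoveryConfig(30000, seed = 2))
  flt <- filterCohort(sim$cohort)$cohort
  tb <- tabulateByAge(flt, "maternal")
  ind <- independentBetaCurve(tb, "preterm", seed = 3)
  tbl <- curveTable(ind)
  expect_identical(tbl$or[tbl$age == 15], 1)
  expect_true(all(tbl$lo <= tbl$or & tbl$or <= tbl$hi))
})

test_that("presets restrict and report the documented populations", {
  oc <- list(preterm = outcomeSpec(0.1, orDS = 5, orCD = 5))
  cfg <- simConfig(4000, outcomes = oc,
                   dsRisk = list(baseline = 0.02, knot = 30, slope = 0.1),
                   cdRisk = list(baseline = 0.02, knot = 30, slope = 0.1),
                   seed = 10)
  flt <- filterCohort(simulateCohort(cfg)$cohort)$cohort
  rec <- birthRecords(flt)
  expect_gt(sum(rec$ds | rec$cd), 0)

  short <- shortConfig(seed = 5, iterations = 600, thin = 2, burnIn = 100)
  tot <- runPreset(flt, "total_maternal", outcomes = "preterm",
                   config = short)
  adj <- runPreset(flt, "adjusted_maternal", outcomes = "preterm",
                   config = short)
  expect_equal(ageAxis(tot$preterm$curve), "maternal")
  expect_equal(tot$preterm$curve@source, "total")
  expect_equal(adj$preterm$curve@source, "adjusted")
  ## adjusted_maternal uses strictly fewer records: visible in the
  ## denominators of the fitted tables via the total number of births
  expect_equal(sum(outcomeCounts(tabulateByAge(flt, "maternal"),
                                 "preterm")$n), nrow(rec))
  nNeg <- sum(!rec$ds & !rec$cd)
  expect_lt(nNeg, nrow(rec))

  adjP <- runPreset(flt, "adjusted_paternal", outcomes = "preterm",
                    config = short)
  expect_equal(ageAxis(adjP$preterm$curve), "paternal")
  expect_error(runPreset(flt, "bogus"), "arg")
})
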