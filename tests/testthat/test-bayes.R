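test_that("RW1 log prior matches hand-computed increment sums", {
  ## zero increments: density term vanishes at sd = 1
  expect_equal(rwLogPrior(rep(0.7, 5), sd = 1), 0)
  ## increments 1 and 2: -(1 + 4)/2
  expect_equal(rwLogPrior(c(0, 1, 3), sd = 1), -2.5)
  ## doubling sd with zero increments costs (K-1) log 2
  K <- 7
  expect_equal(rwLogPrior(rep(0, K), 1) - rwLogPrior(rep(0, K), 2),
               (K - 1) * log(2))
  ## out-of-bounds sd is a rejected state, not an error
  expect_identical(rwLogPrior(c(0, 1), sd = -1), -Inf)
  expect_identical(rwLogPrior(c(0, 1), sd = 11), -Inf)
})

test_that("binomial-logit log likelihood matches closed forms", {
  ## one cell, p = 0.5
  expect_equal(
    binomialLogitLoglik(list(Y = 1, n = 2), alpha = 0,
                        effects = list(maternal = 0)),
    2 * log(0.5)
  )
  ## no data at all
  expect_equal(
    binomialLogitLoglik(list(Y = rep(0, 4), n = rep(0, 4)), alpha = 2,
                        effects = list(maternal = c(1, -1, 2, -2))),
    0
  )
  expect_error(
    binomialLogitLoglik(list(Y = 3, n = 2), alpha = 0,
                        effects = list(maternal = 0)),
    "Y > n"
  )
})

test_that("table log likelihood equals a per-record Bernoulli oracle", {
  sim <- simulateCohort(simConfig(50, seed = 88,
                                  maternal = list(mean = 29, sd = 6,
                                                  span = c(15, 49)),
                                  paternalMissing = list(base = 0, young = 0,
                                                         cutoff = 18)))
  flt <- filterCohort(sim$cohort)$cohort
  tb <- tabulateByAge(flt, "maternal")
  span <- 15:49
  set.seed(1)
  effects <- rnorm(length(span), 0, 0.3)
  alpha <- -1.2
  got <- binomialLogitLoglik(tb, "preterm", alpha,
                             effects = list(maternal = effects))
  rec <- birthRecords(flt)
  p <- plogis(alpha + effects[match(rec$mage, span)])
  oracle <- sum(dbinom(as.integer(rec$preterm), 1, p, log = TRUE))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("shifting alpha against the effects leaves the likelihood invariant", {
  sim <- simulateCohort(simConfig(2000, seed = 12))
  flt <- filterCohort(sim$cohort)$cohort
  jt <- tabulateJoint(flt)
  set.seed(2)
  em <- rnorm(35, 0, 0.2); ep <- rnorm(51, 0, 0.2)
  base <- binomialLogitLoglik(jt, "nicu", -2,
                              effects = list(maternal = em, paternal = ep))
  for (c in c(0.5, -1.3)) {
    shifted <- binomialLogitLoglik(
      jt, "nicu", -2 + c,
      effects = list(maternal = em - c / 2, paternal = ep - c / 2))
    expect_equal(shifted, base, tolerance = 1e-9)
  }
})

test_that("sampler is bit-reproducible from its seed", {
  tb <- list(Y = c(3, 5, 2), n = c(20, 20, 20))
  spec <- tinySpec(3)
  cfg <- shortConfig(seed = 123)
  d1 <- samplePosterior(tb, spec = spec, config = cfg)
  d2 <- samplePosterior(tb, spec = spec, config = cfg)
  expect_identical(chainList(d1), chainList(d2))
  d3 <- samplePosterior(tb, spec = spec, config = shortConfig(seed = 124))
  expect_false(identical(chainList(d1), chainList(d3)))
})

test_that("stored effect draws satisfy the sum-to-zero constraint", {
  sim <- simulateCohort(simConfig(3000, seed = 4))
  flt <- filterCohort(sim$cohort)$cohort
  d <- samplePosterior(tabulateJoint(flt), "preterm",
                       config = shortConfig(seed = 6, iterations = 1000,
                                            thin = 2, burnIn = 200))
  dm <- drawMatrix(d)
  em <- dm[, paste0("maternal_", 15:49)]
  ep <- dm[, paste0("paternal_", 15:65)]
  expect_lt(max(abs(rowSums(em))), 1e-10)
  expect_lt(max(abs(rowSums(ep))), 1e-10)
  expect_true(all(dm[, "sd_maternal"] > 0 & dm[, "sd_maternal"] < 10))
})

test_that("a single-age model recovers the empirical logit", {
  spec <- tinySpec(1)
  d <- samplePosterior(list(Y = 500, n = 1000), spec = spec,
                       config = mcmcConfig(2, 1000, 20000, 10, seed = 2))
  dm <- drawMatrix(d)
  ## the lone effect is pinned at zero by the constraint
  expect_lt(max(abs(dm[, "maternal_15"])), 1e-12)
  expect_lt(abs(mean(dm[, "alpha"])), 0.05)
})

test_that("an all-empty table returns the prior for sd", {
  spec <- tinySpec(5)
  ## the no-data sd chain is a slow random walk over (0, 10), so a long
  ## thinned chain is needed before the mean stabilizes near the prior mean
  d <- samplePosterior(list(Y = rep(0, 5), n = rep(0, 5)), spec = spec,
                       config = mcmcConfig(1, 1000, 100000, 50, seed = 8))
  sdd <- drawMatrix(d)[, "sd_maternal"]
  expect_gt(mean(sdd), 4.6)   # Uniform(0,10) mean is 5
  expect_lt(mean(sdd), 5.4)
})

test_that("span or axis mismatches raise argument errors", {
  tb <- list(Y = c(1, 2), n = c(10, 10))
  expect_error(samplePosterior(tb, spec = tinySpec(3)), "span mismatch")
  sim <- simulateCohort(simConfig(500, seed = 1))
  flt <- filterCohort(sim$cohort)$cohort
  expect_error(
    samplePosterior(tabulateByAge(flt, "maternal"), "preterm",
                    spec = modelSpec("paternal")),
    "axes"
  )
})

test_that("grid oracle honours symmetry and refuses large spans", {
  o <- gridPosteriorOracle(c(4, 4), c(25, 25), fixedSd = 1)
  expect_equal(unname(o$mean[c("effect_1", "effect_2")]), c(0, 0),
               tolerance = 1e-8)
  expect_error(gridPosteriorOracle(rep(1, 5), rep(10, 5), 1), "refuses")
})

test_that("tightening the oracle grid shrinks its error estimate", {
  Y <- c(1, 5, 1); n <- c(10, 10, 10)
  coarse <- gridPosteriorOracle(Y, n, 1, gridSpec = list(
    nAlpha = 31, nEffect = 31, alphaHalfWidth = 4, effectHalfWidth = 4))
  fine <- gridPosteriorOracle(Y, n, 1, gridSpec = list(
    nAlpha = 121, nEffect = 121, alphaHalfWidth = 4, effectHalfWidth = 4))
  expect_lt(fine$errorEstimate, coarse$errorEstimate)
  expect_equal(unname(fine$mean), unname(coarse$mean), tolerance = 0.01)
})

test_that("split-Rhat separates identical, mixed and divergent chains", {
  set.seed(31)
  base <- matrix(rnorm(600), 200, 3,
                 dimnames = list(NULL, c("alpha", "maternal_15", "sd_maternal")))
  mk <- function(chains) {
    new("PosteriorDraws", chains = chains, modelSpec = tinySpec(1),
        mcmcConfig = mcmcConfig(length(chains), 0, 200, 1),
        outcome = "x", acceptance = c(alpha = 0.4))
  }
  same <- computeRhat(mk(list(base, base)))
  ## split-Rhat of duplicated chains is sqrt((n-1)/n + B/(nW)) with a small
  ## between-half term, so it sits near - not exactly at - 1
  expect_equal(max(same@stats$rhat), 1, tolerance = 5e-3)
  expect_true(same@converged)

  offset <- base; offset[, "alpha"] <- offset[, "alpha"] + 50
  div <- computeRhat(mk(list(base, offset)))
  expect_gt(div@stats$rhat[div@stats$parameter == "alpha"], 2)
  expect_false(div@converged)

  expect_error(computeRhat(mk(list(base))), "2 chains")
})

test_that("a well-mixed run on the 3-age model converges by split-Rhat", {
  d <- samplePosterior(list(Y = c(1, 5, 1), n = c(10, 10, 10)),
                       spec = tinySpec(3, sdFixed = 1),
                       config = mcmcConfig(2, 2000, 20000, 10, seed = 44))
  rep <- computeRhat(d)
  expect_true(rep@converged)
  expect_lt(max(rep@stats$rhat), 1.05)
})

test_that("draws round-trip through the CSV + JSON serialization", {
  d <- samplePosterior(list(Y = c(2, 3), n = c(15, 15)),
                       spec = tinySpec(2),
                       config = shortConfig(seed = 10, iterations = 200,
                                            thin = 2, burnIn = 100))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDraws(d, path)
  back <- readDraws(path)
  expect_equal(chainList(back), chainList(d))
  expect_equal(back@modelSpec@spans, d@modelSpec@spans)
  expect_equal(back@mcmcConfig@seed, d@mcmcConfig@seed)
})
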