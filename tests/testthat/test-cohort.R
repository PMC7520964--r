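test_that("CSV schema round-trips, including missing values and flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "mage,page,ds,cd,preterm,very_preterm,sga,low_apgar,nicu,antibiotics,surfactant,prolonged_ventilation,seizures,death",
    "20,25,0,0,1,0,0,0,0,0,0,0,0,0",
    "30,31,1,0,0,0,0,0,1,0,0,0,0,0",
    "28,,0,1,0,0,,0,0,0,0,0,0,0"
  ), path)
  bc <- readBirths(path)
  expect_equal(nBirths(bc), 3)
  rec <- birthRecords(bc)
  expect_equal(rec$mage, c(20L, 30L, 28L))
  expect_equal(rec$page, c(25L, 31L, NA))
  expect_identical(rec$ds, c(FALSE, TRUE, FALSE))
  expect_identical(rec$sga, c(FALSE, FALSE, NA))

  out <- withr::local_tempfile(fileext = ".csv")
  writeBirths(bc, out)
  again <- readBirths(out)
  expect_identical(birthRecords(again), birthRecords(bc))
})

test_that("header-only file yields an empty cohort; schema errors are caught", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("mage,page,ds,cd", path)
  expect_equal(nBirths(readBirths(path)), 0)

  writeLines(c("page,ds", "25,0"), path)
  expect_error(readBirths(path), "mage")

  writeLines(c("mage,page", "twenty,25"), path)
  expect_error(readBirths(path), "row 1")

  writeLines(c("mage,bogus", "20,1"), path)
  expect_warning(readBirths(path), "bogus")
})

test_that("simulated cohorts survive a write-then-read round trip", {
  sim <- simulateCohort(simConfig(500, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  writeBirths(sim$cohort, path)
  back <- readBirths(path)
  expect_identical(birthRecords(back)[, names(birthRecords(sim$cohort))],
                   birthRecords(sim$cohort))
})

test_that("filterCohort applies range rules with correct precedence", {
  bc <- makeCohort(mage = c(14, rep(30, 9)), page = c(40, rep(35, 9)))
  res <- filterCohort(bc)
  expect_equal(nBirths(res$cohort), 9)
  expect_equal(res$report@nMotherUnderMin, 1L)
  expect_equal(res$report@nDeletedForParentAge, 1L)

  ## missing father excluded under the father category
  bc2 <- makeCohort(mage = 30, page = NA)
  res2 <- filterCohort(bc2)
  expect_equal(res2$report@nFatherOutOfRangeOrMissing, 1L)
  expect_equal(nBirths(res2$cohort), 0)

  ## a record violating both mother and outcome rules counts once, under
  ## parent age
  rec <- makeRecords(mage = 14, page = 30)
  rec$death <- NA
  res3 <- filterCohort(birthCohort(rec))
  expect_equal(res3$report@nMotherUnderMin, 1L)
  expect_equal(res3$report@nDeletedForMissingOutcome, 0L)

  expect_error(filterCohort(bc, maternalRange = c(49, 15)), "inverted")
})

test_that("filter conservation identity holds and matches planted counts", {
  sim <- simulateCohort(simConfig(30000, seed = 17))
  res <- filterCohort(sim$cohort)
  cts <- filterCounts(res$report)
  expect_equal(cts[["nRetained"]],
               cts[["nInput"]] - cts[["nDeletedForParentAge"]] -
                 cts[["nDeletedForMissingOutcome"]])
  planted <- sim$truth$planted
  for (nm in names(planted)) {
    expect_equal(unname(cts[[nm]]), unname(planted[[nm]]), label = nm)
  }
})

test_that("deriveSGA flags the lowest decile per gestation day", {
  ## 20 births on one day, weights 100..2000: type-7 10th pct = 290
  rec <- makeRecords(mage = rep(30, 20), page = 35,
                     birthweight_g = seq(100L, 2000L, by = 100L),
                     gestation_days = 273L)
  out <- birthRecords(deriveSGA(birthCohort(rec)))
  expect_identical(which(out$sga), 1:2)

  ## identical weights: nothing strictly below the threshold
  rec2 <- makeRecords(mage = rep(30, 12), page = 35,
                      birthweight_g = 3000L, gestation_days = 270L)
  out2 <- birthRecords(deriveSGA(birthCohort(rec2)))
  expect_false(any(out2$sga))

  ## two disjoint gestation-day groups get independent thresholds
  rec3 <- makeRecords(mage = rep(30, 40), page = 35,
                      birthweight_g = c(seq(100L, 2000L, 100L),
                                        seq(3100L, 5000L, 100L)),
                      gestation_days = rep(c(250L, 280L), each = 20))
  out3 <- birthRecords(deriveSGA(birthCohort(rec3)))
  expect_identical(which(out3$sga), c(1:2, 21:22))

  ## small cells warn but still compute
  rec4 <- makeRecords(mage = rep(30, 5), page = 35,
                      birthweight_g = c(100L, 200L, 300L, 400L, 500L),
                      gestation_days = 260L)
  expect_warning(deriveSGA(birthCohort(rec4)), "fewer than 10")
})

test_that("deriveSGA flags about 10% of a large continuous-weight group", {
  set.seed(42)
  n <- 10000
  rec <- makeRecords(mage = rep(30, n), page = 35,
                     birthweight_g = as.integer(round(rnorm(n, 3400, 450))),
                     gestation_days = 273L)
  out <- birthRecords(deriveSGA(birthCohort(rec)))
  expect_gt(mean(out$sga), 0.09)
  expect_lt(mean(out$sga), 0.11)
})

test_that("tabulateByAge counts directly and spans the full grid", {
  rec <- makeRecords(mage = rep(30, 4), page = 35)
  rec$death[2] <- TRUE
  tb <- tabulateByAge(birthCohort(rec), "maternal")
  oc <- outcomeCounts(tb, "death")
  expect_equal(oc$rowData$age, 15:49)
  expect_equal(oc$Y[oc$rowData$age == 30], 1L)
  expect_equal(oc$n[oc$rowData$age == 30], 4L)
  expect_equal(sum(oc$n), 4L)

  empty <- tabulateByAge(birthCohort(makeRecords(integer(0))), "paternal")
  expect_equal(dim(empty), c(51L, 10L))
  expect_true(all(SummarizedExperiment::assay(empty, "n") == 0))
})

test_that("age-table sums equal whole-cohort outcome totals", {
  sim <- simulateCohort(simConfig(5000, seed = 9))
  flt <- filterCohort(sim$cohort)$cohort
  tb <- tabulateByAge(flt, "maternal")
  rec <- birthRecords(flt)
  for (oc in nmmOutcomes()) {
    cc <- outcomeCounts(tb, oc)
    expect_equal(sum(cc$Y), sum(rec[[oc]]), label = oc)
    expect_equal(sum(cc$n), nrow(rec), label = oc)
  }
})

test_that("joint table is complete and marginalizes to the axis tables", {
  rec <- makeRecords(mage = 30, page = 35)
  rec$nicu <- TRUE
  jt <- tabulateJoint(birthCohort(rec))
  expect_equal(nrow(jt), 35L * 51L)
  Y <- SummarizedExperiment::assay(jt, "Y")[, "nicu"]
  expect_equal(sum(Y > 0), 1L)
  rd <- SummarizedExperiment::rowData(jt)
  expect_equal(rd$mage[which(Y > 0)], 30L)
  expect_equal(rd$page[which(Y > 0)], 35L)

  sim <- simulateCohort(simConfig(8000, seed = 21))
  flt <- filterCohort(sim$cohort)$cohort
  jt <- tabulateJoint(flt)
  rd <- SummarizedExperiment::rowData(jt)
  for (axis in c("maternal", "paternal")) {
    uni <- tabulateByAge(flt, axis)
    key <- if (axis == "maternal") rd$mage else rd$page
    for (oc in c("preterm", "death")) {
      jc <- outcomeCounts(jt, oc)
      uc <- outcomeCounts(uni, oc)
      margY <- as.vector(rowsum(jc$Y, key))
      margN <- as.vector(rowsum(jc$n, key))
      expect_equal(margY, as.vector(uc$Y), label = paste(axis, oc, "Y"))
      expect_equal(margN, as.vector(uc$n), label = paste(axis, oc, "n"))
    }
  }
})

test_that("tabulateBinary separates DS and non-DS chromosomal exposures", {
  rec <- makeRecords(mage = rep(30, 4), page = 35,
                     ds = c(TRUE, TRUE, FALSE, FALSE))
  rec$death <- c(TRUE, FALSE, TRUE, FALSE)
  tb <- tabulateBinary(birthCohort(rec), "ds")
  row <- tb@counts[tb@counts$outcome == "death", ]
  expect_equal(row$casesExposed, 1)
  expect_equal(row$birthsExposed, 2)
  expect_equal(row$casesUnexposed, 1)
  expect_equal(row$birthsUnexposed, 2)

  ## ds=TRUE, cd=FALSE is unexposed for the cd exposure
  rec2 <- makeRecords(mage = rep(30, 3), page = 35,
                      ds = c(TRUE, FALSE, FALSE), cd = c(FALSE, TRUE, FALSE))
  tb2 <- tabulateBinary(birthCohort(rec2), "cd")
  expect_equal(tb2@counts$birthsExposed[1], 1)
  expect_equal(tb2@counts$birthsUnexposed[1], 2)

  ## all-unexposed cohort
  tb3 <- tabulateBinary(birthCohort(makeRecords(mage = rep(30, 5), page = 35)),
                        "ds")
  expect_true(all(tb3@counts$birthsExposed == 0))
})

test_that("binary counts agree with per-record brute force", {
  sim <- simulateCohort(simConfig(20000, seed = 31))
  flt <- filterCohort(sim$cohort)$cohort
  rec <- birthRecords(flt)
  tb <- tabulateBinary(flt, "cd")
  for (oc in c("preterm", "nicu", "death")) {
    row <- tb@counts[tb@counts$outcome == oc, ]
    expect_equal(row$casesExposed, sum(rec[[oc]][rec$cd], na.rm = TRUE))
    expect_equal(row$casesUnexposed, sum(rec[[oc]][!rec$cd], na.rm = TRUE))
  }
})

test_that("count tables round-trip through the long CSV format", {
  sim <- simulateCohort(simConfig(3000, seed = 5))
  flt <- filterCohort(sim$cohort)$cohort
  for (tb in list(tabulateByAge(flt, "maternal"), tabulateJoint(flt))) {
    path <- withr::local_tempfile(fileext = ".csv")
    writeCountTable(tb, path)
    back <- readCountTable(path)
    expect_identical(SummarizedExperiment::assay(back, "Y"),
                     SummarizedExperiment::assay(tb, "Y"))
    expect_identical(SummarizedExperiment::assay(back, "n"),
                     SummarizedExperiment::assay(tb, "n"))
  }
})
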