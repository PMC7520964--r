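## Orchestration and reporting: JSON/CSV artifact writers that round-trip
## through the package, a config hash for traceability, the end-to-end
## pipeline, and a small subcommand-style command-line front end (see
## inst/exec/nmmbayes).

#' Hash a configuration object for log traceability
#'
#' @param x Any R object (typically a config list or S4 object).
#' @return Character hash.
#' @export
configHash <- function(x) rlang::hash(x)

#' Write a filter report as JSON
#'
#' @param report A [FilterReport].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(as.list(filterCounts(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a filter report written by [writeFilterReport()]
#'
#' @param path JSON path.
#' @return A [FilterReport].
#' @export
readFilterReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FilterReport",
    nInput = as.integer(x$nInput),
    nMotherUnderMin = as.integer(x$nMotherUnderMin),
    nMotherOverMax = as.integer(x$nMotherOverMax),
    nFatherOutOfRangeOrMissing = as.integer(x$nFatherOutOfRangeOrMissing),
    nDeletedForParentAge = as.integer(x$nDeletedForParentAge),
    nDeletedForMissingOutcome = as.integer(x$nDeletedForMissingOutcome),
    nRetained = as.integer(x$nRetained)
  )
}

#' Write a count table in long CSV format
#'
#' Age tables become `outcome,age,Y,n`; joint tables become
#' `outcome,mage,page,Y,n`. Integer cells are written exactly.
#'
#' @param table An [AgeOutcomeTable] or [JointAgeOutcomeTable].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(table, path) {
  rd <- as.data.frame(SummarizedExperiment::rowData(table))
  Y <- SummarizedExperiment::assay(table, "Y")
  n <- SummarizedExperiment::assay(table, "n")
  long <- do.call(rbind, lapply(colnames(Y), function(oc) {
    cbind(data.frame(outcome = oc), rd, data.frame(Y = Y[, oc], n = n[, oc]))
  }))
  if (is(table, "AgeOutcomeTable")) {
    long$axis <- table@axis
    long <- long[, c("outcome", "axis", "age", "Y", "n")]
  }
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count table written by [writeCountTable()]
#'
#' @param path Long-format CSV path.
#' @return An [AgeOutcomeTable] or [JointAgeOutcomeTable], reconstructed
#'   bit-exactly.
#' @export
readCountTable <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  outs <- unique(long$outcome)
  if ("age" %in% names(long)) {
    axis <- long$axis[1]
    span <- .axisSpan(axis)
    Y <- sapply(outs, function(oc) {
      sub <- long[long$outcome == oc, ]
      sub$Y[match(span, sub$age)]
    })
    n <- sapply(outs, function(oc) {
      sub <- long[long$outcome == oc, ]
      sub$n[match(span, sub$age)]
    })
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(Y = matrix(as.integer(Y), ncol = length(outs),
                               dimnames = list(NULL, outs)),
                    n = matrix(as.integer(n), ncol = length(outs),
                               dimnames = list(NULL, outs))),
      rowData = S4Vectors::DataFrame(age = span),
      colData = S4Vectors::DataFrame(outcome = outs, row.names = outs)
    )
    return(new("AgeOutcomeTable", se, axis = axis))
  }
  grid <- expand.grid(page = .PATERNAL_SPAN, mage = .MATERNAL_SPAN)
  key <- function(m, p) paste(m, p)
  gk <- key(grid$mage, grid$page)
  Y <- sapply(outs, function(oc) {
    sub <- long[long$outcome == oc, ]
    sub$Y[match(gk, key(sub$mage, sub$page))]
  })
  n <- sapply(outs, function(oc) {
    sub <- long[long$outcome == oc, ]
    sub$n[match(gk, key(sub$mage, sub$page))]
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Y = matrix(as.integer(Y), ncol = length(outs),
                             dimnames = list(NULL, outs)),
                  n = matrix(as.integer(n), ncol = length(outs),
                             dimnames = list(NULL, outs))),
    rowData = S4Vectors::DataFrame(mage = grid$mage, page = grid$page),
    colData = S4Vectors::DataFrame(outcome = outs, row.names = outs)
  )
  new("JointAgeOutcomeTable", se)
}

.shapeToList <- function(shape) {
  list(label = shape@label, troughAge = shape@troughAge,
       anySignificant = shape@anySignificant,
       evidence = shape@evidence)
}

#' Write a per-outcome model report as JSON plus a curve CSV
#'
#' The JSON carries the preset, outcome, standardized OR curve, the shape
#' classification with its evidence, pairwise ORs of the span ends against
#' the customary minimum-risk age (maternal 30 / paternal 35), the
#' convergence summary and sampler acceptance rates. The companion CSV
#' (`<path>.curve.csv`) holds the curve table (`age, or, lo, hi, sig`).
#'
#' @param fit One element of a [runPreset()] result.
#' @param preset Preset name.
#' @param outcome Outcome name.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, preset, outcome, path) {
  axis <- fit$curve@axis
  lowRiskAge <- if (axis == "maternal") 30L else 35L
  span <- range(fit$curve@table$age)
  pw <- rbind(pairwiseOR(fit$draws, axis, span[1], lowRiskAge),
              pairwiseOR(fit$draws, axis, span[2], lowRiskAge))
  conv <- fit$convergence
  report <- list(
    preset = preset,
    outcome = outcome,
    referenceAge = fit$curve@referenceAge,
    curve = fit$curve@table,
    classification = .shapeToList(fit$shape),
    pairwiseVsLowRiskAge = pw,
    convergence = if (is.null(conv)) NULL else list(
      maxRhat = max(conv@stats$rhat), converged = conv@converged),
    acceptance = as.list(fit$draws@acceptance)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  write.csv(fit$curve@table, paste0(path, ".curve.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or read) -> filter -> tabulate -> binary DS/CD odds
#' ratios -> preset model fits -> shape classification -> reports, writing
#' every artifact into `outDir`. Convergence failure is reported with a
#' prominent warning but still emits results, since the user may simply
#' extend the chains.
#'
#' @param input A [BirthCohort], a [SimConfig] (simulated on the fly), or
#'   a path to a births CSV.
#' @param outDir Output directory (created if needed).
#' @param presets Character vector of preset names for [runPreset()].
#' @param outcomes Outcomes to fit.
#' @param config An [MCMCConfig].
#' @param referenceAge Reference age for reported curves.
#' @return Invisibly, a list with the filtered cohort, filter report,
#'   binary OR tables, and per-preset fit results.
#' @export
runPipeline <- function(input, outDir,
                        presets = c("total_maternal", "total_paternal",
                                    "adjusted_maternal", "adjusted_paternal"),
                        outcomes = nmmOutcomes(), config = mcmcConfig(),
                        referenceAge = 15L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(list(presets = presets, outcomes = outcomes,
                          mcmc = capture.output(str(config)),
                          referenceAge = referenceAge))
  message("pipeline config hash: ", hash)

  if (is(input, "SimConfig")) {
    message("simulating cohort of ", input@nBirths, " births (seed ",
            input@seed, ", config hash ", configHash(input), ")")
    sim <- simulateCohort(input)
    cohort <- sim$cohort
    jsonlite::write_json(
      list(orDS = as.list(sim$truth$orDS), orCD = as.list(sim$truth$orCD),
           planted = as.list(sim$truth$planted)),
      file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeBirths(cohort, file.path(outDir, "births.csv"))
  } else if (is.character(input)) {
    cohort <- readBirths(input)
  } else {
    cohort <- input
  }

  flt <- filterCohort(cohort)
  message("filter: retained ", flt$report@nRetained, " of ",
          flt$report@nInput, " births")
  writeFilterReport(flt$report, file.path(outDir, "filter_report.json"))
  writeBirths(flt$cohort, file.path(outDir, "births_filtered.csv"))

  writeCountTable(tabulateByAge(flt$cohort, "maternal"),
                  file.path(outDir, "counts_maternal.csv"))
  writeCountTable(tabulateByAge(flt$cohort, "paternal"),
                  file.path(outDir, "counts_paternal.csv"))

  binary <- do.call(rbind, lapply(c("ds", "cd"), function(expo) {
    tb <- tabulateBinary(flt$cohort, expo)
    if (any(tb@counts$birthsExposed == 0)) {
      message("no ", expo, "-exposed births; skipping binary ORs for ", expo)
      return(NULL)
    }
    estimateBinaryOR(tb, seed = config@seed)
  }))
  if (!is.null(binary)) {
    write.csv(binary, file.path(outDir, "binary_or.csv"), row.names = FALSE,
              quote = FALSE)
  }

  fits <- lapply(setNames(presets, presets), function(ps) {
    message("fitting preset ", ps)
    res <- runPreset(flt$cohort, ps, outcomes = outcomes, config = config,
                     referenceAge = referenceAge)
    for (oc in names(res)) {
      fit <- res[[oc]]
      message(sprintf("  %s: shape %s, acceptance %s", oc,
                      fit$shape@label,
                      paste(sprintf("%s=%.2f", names(fit$draws@acceptance),
                                    fit$draws@acceptance), collapse = " ")))
      if (!is.null(fit$convergence)) {
        if (!fit$convergence@converged) {
          warning("preset ", ps, ", outcome ", oc,
                  ": chains NOT converged (max Rhat = ",
                  format(max(fit$convergence@stats$rhat), digits = 4),
                  "); results emitted anyway -- consider longer chains",
                  immediate. = TRUE)
        } else {
          message(sprintf("  %s: max Rhat %.4f", oc,
                          max(fit$convergence@stats$rhat)))
        }
      }
      writeFitReport(fit, ps, oc,
                     file.path(outDir, sprintf("report_%s_%s.json", ps, oc)))
      writeDraws(fit$draws,
                 file.path(outDir, sprintf("draws_%s_%s.csv", ps, oc)))
    }
    res
  })

  invisible(list(cohort = flt$cohort, report = flt$report, binary = binary,
                 fits = fits))
}

## ---- command-line front end -------------------------------------------

.cliUsage <- function() {
  cat("usage: nmmbayes <subcommand> [--flag value ...]\n",
      "subcommands:\n",
      "  simulate  --n N --seed S --out births.csv [--truth truth.json]\n",
      "  filter    --in births.csv --out filtered.csv --report report.json\n",
      "  tabulate  --in filtered.csv --axis maternal|paternal|joint --out counts.csv\n",
      "  fit-binary --in filtered.csv --exposure ds|cd --out or.csv [--seed S]\n",
      "  fit       --in filtered.csv --preset P --outcome OC --out draws.csv\n",
      "            [--chains C --burnin B --iterations I --thin T --seed S]\n",
      "  classify  --draws draws.csv --axis A --out shape.json\n",
      "  report    --draws draws.csv --axis A --ref 15 --out curve.csv\n",
      "  all       --n N --seed S --outdir DIR [--iterations I --burnin B\n",
      "             --thin T --chains C --outcomes a,b,c]\n", sep = "")
}

.cliFlags <- function(argv) {
  flags <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(argv)) stop("flag ", a, " needs a value")
    flags[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  flags
}

.cliMcmc <- function(f) {
  mcmcConfig(
    nChains = as.integer(f$chains %||% 2L),
    burnIn = as.integer(f$burnin %||% 5000L),
    iterations = as.integer(f$iterations %||% 200000L),
    thin = as.integer(f$thin %||% 100L),
    seed = as.integer(f$seed %||% 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches the subcommands of the `nmmbayes` executable script (under
#' `inst/exec/`). Unknown subcommands or flags print usage and return exit
#' code 2; any other error prints a diagnostic and returns 1; convergence
#' failures warn but still emit results and return 0.
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit code.
#' @export
nmmCliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { .cliUsage(); return(2L) }
  sub <- argv[1]
  known <- c("simulate", "filter", "tabulate", "fit-binary", "fit",
             "classify", "report", "all")
  if (!sub %in% known) { .cliUsage(); return(2L) }
  res <- tryCatch({
    f <- .cliFlags(argv[-1])
    message("config hash: ", configHash(list(sub = sub, flags = f)))
    switch(sub,
      simulate = {
        cfg <- simConfig(as.integer(f$n %||% 10000L),
                         seed = as.integer(f$seed %||% 1L))
        sim <- simulateCohort(cfg)
        writeBirths(sim$cohort, f$out %||% "births.csv")
        if (!is.null(f$truth)) {
          jsonlite::write_json(
            list(orDS = as.list(sim$truth$orDS),
                 orCD = as.list(sim$truth$orCD),
                 planted = as.list(sim$truth$planted)),
            f$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        }
      },
      filter = {
        flt <- filterCohort(readBirths(f$`in`))
        writeBirths(flt$cohort, f$out %||% "filtered.csv")
        writeFilterReport(flt$report, f$report %||% "filter_report.json")
        show(flt$report)
      },
      tabulate = {
        cohort <- readBirths(f$`in`)
        tb <- if ((f$axis %||% "maternal") == "joint") tabulateJoint(cohort)
              else tabulateByAge(cohort, f$axis %||% "maternal")
        writeCountTable(tb, f$out %||% "counts.csv")
      },
      `fit-binary` = {
        cohort <- readBirths(f$`in`)
        tb <- tabulateBinary(cohort, f$exposure %||% "ds")
        or <- estimateBinaryOR(tb, seed = as.integer(f$seed %||% 1L))
        write.csv(or, f$out %||% "binary_or.csv", row.names = FALSE,
                  quote = FALSE)
      },
      fit = {
        cohort <- readBirths(f$`in`)
        fit <- runPreset(cohort, f$preset %||% "total_maternal",
                         outcomes = f$outcome %||% "preterm",
                         config = .cliMcmc(f))
        fit <- fit[[1]]
        writeDraws(fit$draws, f$out %||% "draws.csv")
        if (!is.null(fit$convergence) && !fit$convergence@converged) {
          warning("chains NOT converged; results emitted anyway",
                  immediate. = TRUE)
        }
      },
      classify = {
        draws <- readDraws(f$draws)
        shape <- classifyShape(draws, f$axis %||% "maternal")
        jsonlite::write_json(.shapeToList(shape), f$out %||% "shape.json",
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows")
        show(shape)
      },
      report = {
        draws <- readDraws(f$draws)
        curve <- orCurve(draws, f$axis %||% "maternal",
                         referenceAge = as.integer(f$ref %||% 15L))
        write.csv(curve@table, f$out %||% "curve.csv", row.names = FALSE,
                  quote = FALSE)
      },
      all = {
        cfg <- simConfig(as.integer(f$n %||% 10000L),
                         seed = as.integer(f$seed %||% 1L))
        outcomes <- if (is.null(f$outcomes)) nmmOutcomes()
                    else strsplit(f$outcomes, ",")[[1]]
        runPipeline(cfg, f$outdir %||% "nmm_run",
                    outcomes = outcomes, config = .cliMcmc(f))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}
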