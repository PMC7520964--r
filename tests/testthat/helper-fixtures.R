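## Shared fixture builders. Everything is generated in code; no data files.

## small record table with full schema defaults
makeRecords <- function(mage, page = NA, ds = FALSE, cd = FALSE, ...) {
  n <- length(mage)
  rec <- data.frame(mage = mage, page = rep_len(page, n))
  rec$ds <- rep_len(ds, n)
  rec$cd <- rep_len(cd, n)
  for (oc in nmmOutcomes()) rec[[oc]] <- rep(FALSE, n)
  extra <- list(...)
  for (nm in names(extra)) rec[[nm]] <- rep_len(extra[[nm]], n)
  rec
}

makeCohort <- function(...) birthCohort(makeRecords(...), provenance = "test")

## model spec over a tiny contiguous maternal span
tinySpec <- function(K, sdFixed = NA_real_, sdUpper = 10) {
  modelSpec("maternal", spans = list(maternal = seq(15L, 15L + K - 1L)),
            sdUpper = sdUpper, sdFixed = c(maternal = sdFixed))
}

shortConfig <- function(seed = 1L, nChains = 2L, burnIn = 500L,
                        iterations = 4000L, thin = 4L) {
  mcmcConfig(nChains, burnIn, iterations, thin, seed = seed)
}

## synthetic PosteriorDraws with prescribed effect draws (draws x ages)
syntheticDraws <- function(effects, axis = "maternal",
                           span = 15L + seq_len(ncol(effects)) - 1L) {
  colnames(effects) <- paste0(axis, "_", span)
  dm <- cbind(alpha = rep(0, nrow(effects)), effects)
  dm <- cbind(dm, setNames(data.frame(rep(1, nrow(effects))),
                           paste0("sd_", axis)))
  dm <- as.matrix(dm)
  spec <- modelSpec(axis, spans = setNames(list(as.integer(span)), axis))
  new("PosteriorDraws", chains = list(dm), modelSpec = spec,
      mcmcConfig = mcmcConfig(1, 0, nrow(effects), 1),
      outcome = "synthetic", acceptance = c(alpha = 0.4))
}

## effect draws from a deterministic mean curve plus iid normal noise
curveDraws <- function(means, se, nDraws = 2000, seed = 99,
                       axis = "maternal") {
  set.seed(seed)
  e <- sapply(means, function(m) rnorm(nDraws, m, se))
  syntheticDraws(e, axis = axis)
}

## the parameter-recovery scenario: one outcome, distinct parental curves,
## strong DS/CD odds multipliers, correlated ages. Paternal ages are fully
## observed here so the confounding path is not partially cancelled by the
## young-mother missing-father selection effect.
recoveryConfig <- function(n = 100000, seed = 1) {
  oc <- list(preterm = outcomeSpec(
    0.08,
    maternalCurve = ageCurve(30, 0.6 / 225, 0.8 / 361),
    paternalCurve = ageCurve(35, 0.5 / 400, 0.9 / 900),
    orDS = 5, orCD = 10
  ))
  simConfig(n, outcomes = oc,
            paternalMissing = list(base = 0, young = 0, cutoff = 18),
            seed = seed)
}
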