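## Binomial-logit likelihood, RW1 (intrinsic CAR) age priors, the
## Metropolis-within-Gibbs front end, a quadrature oracle for small
## fixtures, and split-Rhat convergence diagnostics.

#' Construct a ModelSpec
#'
#' @param axes Character vector: `"maternal"`, `"paternal"` or both.
#' @param spans Named list of contiguous integer age spans per axis;
#'   defaults to the study spans (maternal 15-49, paternal 15-65).
#' @param sdUpper Upper bound of the Uniform(0, `sdUpper`) hyperprior on
#'   each random-walk standard deviation.
#' @param sdFixed Named numeric vector; give an axis a finite value to fix
#'   its random-walk SD instead of sampling it (validation use).
#' @return A [ModelSpec].
#' @export
#' @examples
#' modelSpec("maternal")
#' modelSpec(c("maternal", "paternal"))
modelSpec <- function(axes, spans = NULL, sdUpper = 10,
                      sdFixed = c(maternal = NA_real_, paternal = NA_real_)) {
  axes <- match.arg(axes, c("maternal", "paternal"), several.ok = TRUE)
  if (is.null(spans)) {
    spans <- lapply(setNames(axes, axes), .axisSpan)
  }
  fixed <- c(maternal = NA_real_, paternal = NA_real_)
  fixed[names(sdFixed)] <- sdFixed
  new("ModelSpec", axes = axes, spans = spans, sdUpper = sdUpper,
      sdFixed = fixed)
}

#' Construct an MCMCConfig
#'
#' Defaults follow the long production protocol: 5,000 burn-in iterations
#' then 200,000 iterations thinned by 100, on 2 chains with disparate
#' starting values. Examples and tests use far shorter chains.
#'
#' @param nChains Number of chains.
#' @param burnIn Burn-in iterations (proposal adaptation happens here).
#' @param iterations Post-burn-in iterations, divisible by `thin`.
#' @param thin Thinning interval.
#' @param seed Integer seed; identical configurations reproduce draws
#'   bit-for-bit.
#' @param adaptDuringBurnIn Adapt proposal scales during burn-in (frozen
#'   afterwards so the post-burn-in chain is Markovian).
#' @param targetAcceptance Target acceptance rate for the single-site
#'   updates (0.44, the usual one-dimensional optimum).
#' @return An [MCMCConfig].
#' @export
mcmcConfig <- function(nChains = 2L, burnIn = 5000L, iterations = 200000L,
                       thin = 100L, seed = 1L, adaptDuringBurnIn = TRUE,
                       targetAcceptance = 0.44) {
  new("MCMCConfig",
    nChains = as.integer(nChains), burnIn = as.integer(burnIn),
    iterations = as.integer(iterations), thin = as.integer(thin),
    seed = as.integer(seed), adaptDuringBurnIn = adaptDuringBurnIn,
    targetAcceptance = targetAcceptance
  )
}

#' RW1 log prior density of an age-effect vector
#'
#' The first-order random-walk (intrinsic CAR) prior penalizes squared
#' differences of adjacent age effects. Up to an additive constant its log
#' density is `-(K-1) log(sd) - sum(diff(effects)^2) / (2 sd^2)`, where `K`
#' is the span length; the rank deficiency of one is resolved elsewhere by
#' the sum-to-zero constraint.
#'
#' @param effects Numeric vector of effects over a contiguous age span.
#' @param sd Random-walk standard deviation.
#' @param sdUpper Upper bound of the uniform hyperprior; `sd` outside
#'   `(0, sdUpper)` returns `-Inf` (a rejected state, not an error).
#' @return Log prior density up to an additive constant.
#' @export
#' @examples
#' rwLogPrior(c(0, 1, 3), sd = 1)  # -(1 + 4)/2 = -2.5
rwLogPrior <- function(effects, sd, sdUpper = 10) {
  if (sd <= 0 || sd >= sdUpper) return(-Inf)
  K <- length(effects)
  -(K - 1) * log(sd) - sum(diff(effects)^2) / (2 * sd^2)
}

.cellLoglik <- function(Y, n, eta) {
  ## Y*log(mu) + (n-Y)*log(1-mu) with logit(mu)=eta, binomial coefficient
  ## omitted; stable for large |eta|; cells with n=0 contribute 0
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(Y * eta - n * lse)
}

#' Binomial-logit log likelihood of a count table
#'
#' Sums `Y*log(mu) + (n-Y)*log(1-mu)` over the table's cells for one
#' outcome, with `logit(mu) = alpha + sum of the axis effects`, omitting
#' the binomial coefficients (constant in the parameters). Cells with
#' `n = 0` contribute zero.
#'
#' @param table An [AgeOutcomeTable] or [JointAgeOutcomeTable], or a list
#'   with elements `Y`, `n` (and `mage`/`page` level indices for two axes).
#' @param outcome Outcome name (ignored when `table` is a list).
#' @param alpha Intercept on the logit scale.
#' @param effects Named list of effect vectors, one per axis in the table
#'   (`maternal` and/or `paternal`), covering the table's age spans.
#' @return Log likelihood (a scalar).
#' @export
binomialLogitLoglik <- function(table, outcome = NULL, alpha, effects) {
  cells <- .modelCells(table, outcome)
  if (any(cells$Y > cells$n)) stop("invariant violation: Y > n")
  eta <- rep(alpha, length(cells$Y))
  if (!is.null(cells$mIdx)) {
    if (length(effects$maternal) != cells$nM) {
      stop("maternal effect vector does not cover the table's age span")
    }
    eta <- eta + effects$maternal[cells$mIdx]
  }
  if (!is.null(cells$pIdx)) {
    if (length(effects$paternal) != cells$nP) {
      stop("paternal effect vector does not cover the table's age span")
    }
    eta <- eta + effects$paternal[cells$pIdx]
  }
  .cellLoglik(cells$Y, cells$n, eta)
}

## Normalize the supported table forms into cell vectors plus 1-based age
## level indices per axis.
.modelCells <- function(table, outcome = NULL, span = NULL) {
  if (is(table, "AgeOutcomeTable")) {
    oc <- outcomeCounts(table, outcome)
    axis <- table@axis
    out <- list(Y = oc$Y, n = oc$n)
    if (axis == "maternal") {
      out$mIdx <- seq_along(oc$Y); out$nM <- length(oc$Y)
    } else {
      out$pIdx <- seq_along(oc$Y); out$nP <- length(oc$Y)
    }
    out$axes <- axis
    out$spans <- setNames(list(as.integer(oc$rowData$age)), axis)
    return(out)
  }
  if (is(table, "JointAgeOutcomeTable")) {
    oc <- outcomeCounts(table, outcome)
    mspan <- sort(unique(oc$rowData$mage))
    pspan <- sort(unique(oc$rowData$page))
    return(list(
      Y = oc$Y, n = oc$n,
      mIdx = match(oc$rowData$mage, mspan),
      pIdx = match(oc$rowData$page, pspan),
      nM = length(mspan), nP = length(pspan),
      axes = c("maternal", "paternal"),
      spans = list(maternal = as.integer(mspan), paternal = as.integer(pspan))
    ))
  }
  if (is.list(table)) {
    out <- list(Y = table$Y, n = table$n)
    if (!is.null(table$mIdx)) { out$mIdx <- table$mIdx; out$nM <- max(table$mIdx) }
    if (!is.null(table$pIdx)) { out$pIdx <- table$pIdx; out$nP <- max(table$pIdx) }
    if (is.null(out$mIdx) && is.null(out$pIdx)) {
      ## one unnamed axis: treat as maternal by default
      out$mIdx <- seq_along(table$Y); out$nM <- length(table$Y)
    }
    out$axes <- c("maternal", "paternal")[c(!is.null(out$mIdx), !is.null(out$pIdx))]
    return(out)
  }
  stop("unsupported table type: ", class(table)[1])
}

#' Draw from the posterior by adaptive Metropolis-within-Gibbs
#'
#' Fits the binomial-logit model with a flat intercept prior and RW1 age
#' priors (Uniform(0, `sdUpper`) hyperpriors on the random-walk SDs) to one
#' outcome's count table. Updates are single-site Gaussian random walks for
#' the intercept and each age effect, and a log-scale random walk for each
#' SD with hard rejection at the prior bounds. Proposal scales adapt during
#' burn-in only. After every sweep each axis's effect vector is recentred
#' to sum to zero with the removed mean absorbed into the intercept, which
#' leaves the likelihood unchanged and pins down the flat direction the
#' intrinsic prior leaves free. Chains start from disparate deterministic
#' initial values and the whole run is reproducible from the seed.
#'
#' @param table An [AgeOutcomeTable], [JointAgeOutcomeTable], or a list
#'   with `Y` and `n` (plus `mIdx`/`pIdx` level indices for two axes) for
#'   small custom fixtures.
#' @param outcome Outcome name (required for table objects).
#' @param spec A [ModelSpec]; defaults to the axes and spans of `table`.
#' @param config An [MCMCConfig].
#' @return A [PosteriorDraws].
#' @export
samplePosterior <- function(table, outcome = NULL, spec = NULL,
                            config = mcmcConfig()) {
  cells <- .modelCells(table, outcome)
  if (is.null(spec)) {
    if (is.null(cells$spans)) {
      stop("spec is required when the table does not carry age spans")
    }
    spec <- modelSpec(cells$axes, spans = cells$spans)
  }
  if (!setequal(spec@axes, cells$axes)) {
    stop("model axes do not match the table's axes")
  }
  for (ax in spec@axes) {
    want <- length(spec@spans[[ax]])
    got <- if (ax == "maternal") cells$nM else cells$nP
    if (want != got) {
      stop("span mismatch for ", ax, " axis: model has ", want,
           " ages, table has ", got)
    }
  }
  hasM <- "maternal" %in% spec@axes
  hasP <- "paternal" %in% spec@axes
  nM <- if (hasM) length(spec@spans$maternal) else 0L
  nP <- if (hasP) length(spec@spans$paternal) else 0L

  ## drop empty cells; they contribute nothing to the likelihood
  keep <- cells$n > 0
  Y <- as.numeric(cells$Y[keep])
  n <- as.numeric(cells$n[keep])
  mIdx <- if (hasM) as.integer(cells$mIdx[keep] - 1L) else integer(0)
  pIdx <- if (hasP) as.integer(cells$pIdx[keep] - 1L) else integer(0)

  sdBound <- function(ax) {
    f <- spec@sdFixed[[ax]]
    if (!is.na(f)) c(f, f) else c(0, spec@sdUpper)
  }
  bM <- if (hasM) sdBound("maternal") else c(0, 0)
  bP <- if (hasP) sdBound("paternal") else c(0, 0)

  totY <- sum(Y); totN <- sum(n)
  alpha0 <- if (totN > 0) qlogis((totY + 0.5) / (totN + 1)) else 0

  parNames <- c("alpha",
    if (hasM) paste0("maternal_", spec@spans$maternal),
    if (hasP) paste0("paternal_", spec@spans$paternal),
    if (hasM) "sd_maternal",
    if (hasP) "sd_paternal")

  sdInit <- function(b, c) {
    if (b[2] - b[1] < 1e-12) return(b[1])
    b[1] + (b[2] - b[1]) * c / (config@nChains + 1)
  }

  set.seed(config@seed)
  chains <- vector("list", config@nChains)
  accSum <- NULL
  for (c in seq_len(config@nChains)) {
    ## disparate starting values: intercept offset alternates sign and
    ## grows with the chain index; SD starts spread across its range
    offset <- (-1)^(c + 1) * 2 * ceiling(c / 2)
    res <- .runMwgChain(
      Y, n, mIdx, pIdx, nM, nP,
      mAge = if (hasM) as.numeric(spec@spans$maternal) else numeric(0),
      pAge = if (hasP) as.numeric(spec@spans$paternal) else numeric(0),
      alphaInit = alpha0 + offset,
      mInit = numeric(nM), pInit = numeric(nP),
      sdMInit = if (hasM) sdInit(bM, c) else 1,
      sdPInit = if (hasP) sdInit(bP, c) else 1,
      sdLoM = bM[1], sdHiM = bM[2], sdLoP = bP[1], sdHiP = bP[2],
      burnIn = config@burnIn, iterations = config@iterations,
      thin = config@thin, adapt = config@adaptDuringBurnIn,
      targetAcc = config@targetAcceptance
    )
    dm <- res$draws
    colnames(dm) <- parNames
    chains[[c]] <- dm
    acc <- res$acceptance
    accSum <- if (is.null(accSum)) acc else accSum + acc
  }
  acc <- accSum / config@nChains
  acc <- acc[!is.na(acc)]
  new("PosteriorDraws", chains = chains, modelSpec = spec,
      mcmcConfig = config,
      outcome = if (is.null(outcome)) NA_character_ else outcome,
      acceptance = acc)
}

#' Posterior moments of a small model by dense quadrature
#'
#' Independent check of the sampler on tiny fixtures: for a single-axis
#' table with at most four age levels and a fixed random-walk SD, computes
#' posterior means and SDs of the intercept and the sum-to-zero constrained
#' age effects by midpoint-rule quadrature over an orthonormal basis of the
#' constrained subspace, with a flat intercept prior on a wide finite
#' window. The returned `errorEstimate` is the largest change in any
#' posterior mean relative to a grid with half the resolution.
#'
#' @param Y,n Integer case and birth counts per age level (length <= 4).
#' @param fixedSd Fixed random-walk standard deviation.
#' @param gridSpec List: `nAlpha`, `nEffect` (points per dimension),
#'   `alphaHalfWidth`, `effectHalfWidth` (window half-widths around the
#'   empirical logit and zero).
#' @return List with named vectors `mean` and `sd` over
#'   `alpha, effect_1..effect_K`, and `errorEstimate`.
#' @export
gridPosteriorOracle <- function(Y, n, fixedSd,
                                gridSpec = list(nAlpha = 81, nEffect = 81,
                                                alphaHalfWidth = 4,
                                                effectHalfWidth = 4)) {
  K <- length(Y)
  if (K > 4) stop("grid oracle refuses more than 4 age levels")
  stopifnot(length(n) == K, all(Y <= n), all(Y >= 0))

  momentsAt <- function(nAlpha, nEffect) {
    alpha0 <- qlogis((sum(Y) + 0.5) / (sum(n) + 1))
    aGrid <- seq(alpha0 - gridSpec$alphaHalfWidth,
                 alpha0 + gridSpec$alphaHalfWidth, length.out = nAlpha)
    zGrid <- seq(-gridSpec$effectHalfWidth, gridSpec$effectHalfWidth,
                 length.out = nEffect)
    ## orthonormal basis of the sum-to-zero subspace
    B <- qr.Q(qr(matrix(1, K, 1)), complete = TRUE)[, -1, drop = FALSE]
    Z <- as.matrix(expand.grid(rep(list(zGrid), K - 1)))
    E <- Z %*% t(B)                      # effect vectors, one per z point
    priorZ <- apply(E, 1, function(e) rwLogPrior(e, fixedSd, sdUpper = Inf))
    lp <- matrix(NA_real_, length(aGrid), nrow(E))
    for (ia in seq_along(aGrid)) {
      eta <- aGrid[ia] + E
      lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
      lp[ia, ] <- as.vector(eta %*% Y - lse %*% n) + priorZ
    }
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    wa <- rowSums(w)                     # marginal weight per alpha point
    wz <- colSums(w)                     # marginal weight per z point
    meanAlpha <- sum(wa * aGrid)
    sdAlpha <- sqrt(max(0, sum(wa * aGrid^2) - meanAlpha^2))
    meanE <- as.vector(t(E) %*% wz)
    sdE <- sqrt(pmax(0, as.vector(t(E^2) %*% wz) - meanE^2))
    list(mean = setNames(c(meanAlpha, meanE),
                         c("alpha", paste0("effect_", seq_len(K)))),
         sd = setNames(c(sdAlpha, sdE),
                       c("alpha", paste0("effect_", seq_len(K)))))
  }

  fine <- momentsAt(gridSpec$nAlpha, gridSpec$nEffect)
  coarse <- momentsAt(max(11, gridSpec$nAlpha %/% 2),
                      max(11, gridSpec$nEffect %/% 2))
  list(mean = fine$mean, sd = fine$sd,
       errorEstimate = max(abs(fine$mean - coarse$mean)))
}

#' Split-Rhat convergence diagnostics
#'
#' Splits each chain in half, computes the potential scale reduction factor
#' (split-Rhat) and an autocorrelation-based effective sample size for
#' every parameter, and flags convergence when the maximum Rhat falls below
#' the threshold. Parameters that are numerically constant (for example a
#' fixed SD) report Rhat = 1.
#'
#' @param draws A [PosteriorDraws] with at least 2 chains and 10 stored
#'   draws per chain.
#' @param threshold Rhat threshold for the converged flag (default 1.05).
#' @return A [ConvergenceReport].
#' @export
computeRhat <- function(draws, threshold = 1.05) {
  chains <- draws@chains
  if (length(chains) < 2) {
    stop("split-Rhat needs at least 2 chains; rerun with nChains >= 2")
  }
  nd <- nrow(chains[[1]])
  if (nd < 10) stop("need at least 10 stored draws per chain")
  half <- nd %/% 2
  splits <- list()
  for (ch in chains) {
    splits <- c(splits, list(ch[seq_len(half), , drop = FALSE],
                             ch[(nd - half + 1):nd, , drop = FALSE]))
  }
  pars <- colnames(chains[[1]])
  stats <- do.call(rbind, lapply(pars, function(p) {
    xs <- lapply(splits, function(s) s[, p])
    mns <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, var, numeric(1))
    W <- mean(vars)
    B <- half * var(mns)
    if (!is.finite(W) || W < 1e-300) {
      return(data.frame(parameter = p, rhat = 1, ess = NA_real_))
    }
    varPlus <- (half - 1) / half * W + B / half
    rhat <- sqrt(varPlus / W)
    ## crude ESS: pooled autocorrelations truncated at first negative lag
    rho <- sapply(seq_len(min(half - 2, 50)), function(lag) {
      mean(vapply(xs, function(x) {
        x1 <- x[seq_len(half - lag)] - mean(x)
        x2 <- x[(lag + 1):half] - mean(x)
        sum(x1 * x2) / ((half - 1) * var(x))
      }, numeric(1)))
    })
    cut <- which(rho < 0)[1]
    if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
    ess <- length(xs) * half / (1 + 2 * sum(rho))
    data.frame(parameter = p, rhat = rhat, ess = ess)
  }))
  new("ConvergenceReport", stats = stats, threshold = threshold,
      converged = max(stats$rhat, na.rm = TRUE) < threshold)
}

#' Serialize posterior draws to CSV with a JSON sidecar
#'
#' Writes draws in long format (`chain, draw, parameter, value`) and a
#' sidecar `<path>.meta.json` carrying the model axes, spans, hyperprior,
#' sampler configuration and acceptance rates. [readDraws()] reverses it.
#'
#' @param draws A [PosteriorDraws].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeDraws <- function(draws, path) {
  long <- do.call(rbind, lapply(seq_along(draws@chains), function(c) {
    dm <- draws@chains[[c]]
    data.frame(
      chain = c,
      draw = rep(seq_len(nrow(dm)), times = ncol(dm)),
      parameter = rep(colnames(dm), each = nrow(dm)),
      value = as.vector(dm)
    )
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  spec <- draws@modelSpec
  cfg <- draws@mcmcConfig
  meta <- list(
    outcome = draws@outcome,
    axes = spec@axes,
    spans = lapply(spec@spans, range),
    sdUpper = spec@sdUpper,
    sdFixed = as.list(spec@sdFixed),
    mcmc = list(nChains = cfg@nChains, burnIn = cfg@burnIn,
                iterations = cfg@iterations, thin = cfg@thin,
                seed = cfg@seed,
                adaptDuringBurnIn = cfg@adaptDuringBurnIn,
                targetAcceptance = cfg@targetAcceptance),
    acceptance = as.list(draws@acceptance)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read posterior draws written by [writeDraws()]
#'
#' @param path CSV path written by [writeDraws()].
#' @return A [PosteriorDraws].
#' @export
readDraws <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  spans <- lapply(meta$spans, function(r) seq(r[1], r[2]))
  sdFixed <- vapply(meta$sdFixed, function(v) {
    if (is.null(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
  }, numeric(1))
  spec <- modelSpec(meta$axes, spans = spans[meta$axes],
                    sdUpper = meta$sdUpper,
                    sdFixed = setNames(sdFixed, names(meta$sdFixed)))
  cfg <- mcmcConfig(meta$mcmc$nChains, meta$mcmc$burnIn,
                    meta$mcmc$iterations, meta$mcmc$thin, meta$mcmc$seed,
                    meta$mcmc$adaptDuringBurnIn, meta$mcmc$targetAcceptance)
  pars <- unique(long$parameter)
  chains <- lapply(sort(unique(long$chain)), function(c) {
    sub <- long[long$chain == c, ]
    dm <- sapply(pars, function(p) sub$value[sub$parameter == p])
    dm <- matrix(dm, ncol = length(pars), dimnames = list(NULL, pars))
    dm
  })
  new("PosteriorDraws", chains = chains, modelSpec = spec, mcmcConfig = cfg,
      outcome = if (is.null(meta$outcome)) NA_character_ else meta$outcome,
      acceptance = unlist(meta$acceptance))
}
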