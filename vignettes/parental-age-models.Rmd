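---
title: "Bayesian parental-age risk curves: model, sampler and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian parental-age risk curves: model, sampler and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `nmmbayes`, the MCMC
sampler that fits it, the odds-ratio and shape-classification machinery, and
the synthetic cohort generator used for validation — including the places
where the modelling choices have real consequences and the known limitations.

## 1. Scientific setting

Large natality registries record, for every birth, the mother's and father's
age and a set of binary neonatal morbidity and mortality (NMM) outcomes —
preterm birth, very preterm birth, low and very low birthweight,
small-for-gestational-age, a low 5-minute Apgar score, assisted ventilation,
NICU admission, surfactant therapy, and neonatal death before certificate
filing. Raw risks plotted against parental age are typically U- or J-shaped:
elevated for the youngest and oldest parents with a trough around age 30
(maternal) or 35 (paternal). Two questions drive the package design:

1. **Smoothing**: one-year age cells at the extremes hold few births, so raw
   per-age odds ratios are noisy exactly where the science happens. The model
   borrows strength across adjacent ages.
2. **Confounding between parents**: maternal and paternal ages are strongly
   correlated (the generator reproduces r ≈ 0.83). A "total" maternal curve
   absorbs part of the paternal effect and vice versa; a joint model
   estimates each parent's curve adjusted for the other.

Because the registry microdata are not redistributable, the package ships a
seeded generator (`simulateCohort()`) whose ground truth is known, so every
claim the package makes about itself is checked by parameter recovery rather
than by anecdote.

## 2. The model

For one outcome, births are cross-tabulated into one-year age cells —
univariate (maternal 15–49 or paternal 15–65) or joint (maternal × paternal).
Cell counts are modelled binomially with a logit link:

$$ Y_c \sim \mathrm{Binomial}(n_c,\ \mu_c), \qquad
   \mathrm{logit}(\mu_c) = \alpha + m_{i(c)} \; [+\; p_{j(c)}] $$

* $\alpha$ has a flat (improper uniform) prior.
* Each age-effect vector ($m$ over 35 maternal levels, $p$ over 51 paternal
  levels) has a first-order random-walk prior — the 1-D intrinsic conditional
  autoregressive prior: independent Normal increments
  $m_{a+1}-m_a \sim N(0, \sigma^2)$.
* Each random-walk standard deviation $\sigma$ has a Uniform(0, 10) prior.

**Identifiability.** A flat intercept plus intrinsic RW priors leaves a flat
ridge: adding a constant to all age effects and subtracting it from $\alpha$
changes nothing. The sampler resolves this by re-centring each age-effect
vector to sum to zero after every sweep, absorbing the removed mean into
$\alpha$. This is the standard projection of the quotient chain onto the
sum-to-zero representative and leaves the likelihood and the RW prior (which
depends only on differences) untouched; it was additionally verified against
a quadrature oracle (Section 4).

Cells with $n_c = 0$ carry no likelihood information and are dropped from the
likelihood; the prior alone interpolates those ages, which is exactly the
smoothing behaviour we want at empty extreme ages.

## 3. The sampler

`samplePosterior()` runs an adaptive Metropolis-within-Gibbs sampler,
implemented in C++ (Rcpp) and driven by R's RNG so `set.seed()` gives
byte-identical output:

* **Single-site moves** for $\alpha$ and every age effect: Gaussian random
  walk, with each proposal's step size adapted in batches of 50 during
  burn-in toward a 0.44 acceptance rate, then frozen — so the post-burn-in
  chain is a genuine fixed Markov kernel.
* **Standard deviations** are updated on the log scale with the Jacobian
  included; proposals outside $(0, \text{sdUpper})$ are rejected, which
  respects the uniform prior exactly.
* **Per-level caching** of cell indices and linear predictors makes one
  sweep O(active cells).

### Exchange moves for joint models

Joint models have a nearly flat likelihood ridge of their own. Because
parental ages are highly correlated, adding a smooth function
$\phi(\text{age})$ to the maternal curve while subtracting the matching
$\phi$ from the paternal curve changes each cell's linear predictor only
through $\phi(\text{mage}) - \phi(\text{page})$ — a function of the (narrow)
parental age gap. Single-site moves traverse this "tilt" direction
diffusively; at practical chain lengths the symptom is split-$\hat{R}$
around 1.05–1.14 concentrated on the end-of-span effects.

The sampler therefore adds two **directional exchange moves** per sweep: a
centred linear and a centred quadratic age basis (centred at the
data-weighted mean age, scaled by 10 years), proposed as
$m_i \mathrel{+}= c\,\phi(\text{age}_i)$, $p_j \mathrel{-}= c\,\phi(\text{age}_j)$
with a scalar Gaussian step $c$, accepted with the full likelihood change and
the RW-prior change on both axes. Step sizes adapt during burn-in like the
single-site moves. With these moves the same chain budgets give
split-$\hat{R} \le 1.02$ on joint fits.

### Convergence reporting

`ConvergenceReport` carries hand-implemented split-$\hat{R}$ and a truncated
autocorrelation ESS for every parameter (the usual helper packages are not
dependencies). Pipeline entry points warn — they do not stop — when
$\hat{R}$ exceeds the configured threshold, so long pipelines fail loudly but
still deliver inspectable output.

## 4. The quadrature oracle

`gridPosteriorOracle()` computes posterior means for small fixed-$\sigma$
models (up to 4 age levels) by direct numerical integration: the sum-to-zero
subspace is parameterized by an orthonormal basis (QR complement of the
constant vector), the integrand is evaluated on a midpoint grid with
log-sum-exp stabilisation, and the error is estimated by comparison with a
half-resolution grid. The MCMC sampler is required (and tested) to reproduce
oracle means to within 0.02 — this is the ground-truth anchor for the whole
inference stack.

## 5. Odds-ratio curves, standardization and shapes

`orCurve()` converts posterior draws into an odds-ratio curve draw-wise:
$\mathrm{OR}_a = \exp(e_a - e_{\text{ref}})$ per draw, then per-age posterior
medians and 95% equal-tailed intervals. Any reference age in the span is
supported; the conventional displays use the trough ages (maternal 30,
paternal 35), and `pairwiseOR()` gives arbitrary age contrasts. Note that
quantile summaries do not commute with reciprocals, so re-referencing a
summarised curve agrees with re-summarising the draws only to interpolation
accuracy.

The reference-age choice matters quantitatively: every standardized OR
shares the reference cell, so a sparse reference (e.g. age 15, ~1% of
births) injects a common noise term that shifts the entire curve. Recovery
experiments in the test suite therefore standardize at the data-dense trough
ages.

A per-age "significance" is reported as the two-sided posterior tail
probability $2\min(P(\mathrm{OR}_a \ge 1), P(\mathrm{OR}_a \le 1))$ —
with non-strict inequalities, so a degenerate curve gives p = 1 at the
reference rather than 0.

**Shape classification** (`classifyShape()`): the trough is the age with the
smallest posterior-median OR (ties to the youngest). The young side is
"elevated" if the youngest-age OR is credibly above 1 (p < 0.05) and its
median exceeds a ratio threshold; similarly the old side. Both sides elevated
is U (or J when the old side's median is clearly above the young side's);
one side elevated gives increasing/decreasing; neither gives flat.

`independentBetaCurve()` provides the unsmoothed comparator: independent
per-age conjugate Beta posteriors, standardized the same way. The
random-walk model's intervals are narrower than the independent intervals at
most ages — that comparison is part of the acceptance tests.

**Binary exposures.** For Down syndrome and cyanotic congenital heart
disease, `estimateBinaryOR()` uses independent Beta(1,1)-binomial posteriors
for the exposed/unexposed risks and summarises the induced OR by Monte-Carlo
draws (median and 95% interval). A 1e6-draw oracle bounds its error in the
tests.

## 6. The synthetic cohort generator

`simulateCohort()` draws a cohort with the schema of natality microdata:

* Maternal age: rounded truncated Normal(28, 6) on [15, 49]; paternal age =
  maternal + an independent gap (mean 2.5), truncated to [15, 65]. This
  reproduces the strong parental-age correlation that makes the joint model
  necessary.
* Outcome risk: logit-linear in the maternal and paternal quadratic
  `ageCurve()`s plus log-odds multipliers for DS and CD exposures; the true
  standardized OR curve for any configuration is available exactly via
  `trueORCurve()`.
* Missingness: a base paternal-age missingness rate plus a much higher rate
  for mothers under 18, echoing registry reality. For records with a missing
  father, the risk is evaluated at maternal age + mean gap (those records
  are removed by the filter anyway, so this choice only affects planted
  bookkeeping, not inference).
* Consistency forcing (very preterm implies preterm), anthropometrics for
  the SGA derivation, and deliberately planted out-of-range/missing records
  whose exact counts are recorded in `$truth$planted` so the filter audit
  can be checked record-for-record.

Two generator behaviours deserve explicit flags because they affect
experimental design:

1. **Missingness is a selection effect.** Dropping father-missing records —
   which are concentrated at young maternal ages — removes part of the
   paternal confounding path from the retained data. In a
   confounding-control experiment this cancels much of the very thing being
   measured, so the package's recovery experiments switch paternal
   missingness off; the default generator keeps it, because it is real.
2. **Joint splits are weakly identified.** With a weak paternal signal the
   hierarchical RW prior can shrink the paternal curve toward flat and
   attribute the shared variation to the mother — confidently. This is a
   property of the model class, not a sampler defect (it persists at
   $\hat{R} \approx 1$). Recovery experiments use paternal curves strong
   enough to be identifiable; applied users should read joint splits with
   this caveat in mind.

## 7. Pipeline, persistence and CLI

`runPipeline()` chains simulate → filter → tabulate → fit → classify →
report, writing plain-text artifacts (CSV for cohorts, count tables and
draws; JSON for filter reports, fit reports and configuration hashes). Every
artifact has a reader that reconstructs the S4 object, and the acceptance
tests require byte-identical artifacts from identical seeds. The `nmmbayes`
command-line tool in `inst/exec/` is a thin wrapper over `nmmCliMain()`, so
the entire CLI surface is testable in-process.

## 8. Problem sizes and budgets

Univariate fits (35 or 51 parameters) take seconds at typical budgets
(2 chains × 20,000 iterations, thinned by 10). Joint fits (86 age effects,
~1,700 active cells at N = 100,000) take tens of seconds. The acceptance
suite — which includes 20 joint-model recovery simulations and 40 shape-
recovery fits at N = 200,000 — completes in well under half an hour on a
single core.

## 9. Limitations

* RW1 only; an RW2 prior would give smoother curvature estimates at the
  extremes but is not implemented.
* The joint model assumes additivity of the parental effects on the logit
  scale; interaction surfaces are out of scope.
* The split of shared parental-age variation is weakly identified (see
  above); adjusted curves should be interpreted with their full posterior
  intervals, never point estimates alone.
* The binary-exposure odds ratios deliberately ignore parental age
  (matching the descriptive use they serve); they are collapsible summaries,
  not adjusted effects.
* SGA uses the empirical type-7 quantile of birthweight within gestation
  day, flagging strictly-below-threshold weights, and warns on cells with
  fewer than 10 births.
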