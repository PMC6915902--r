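---
title: "Auditing epigenetic clock bias: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing epigenetic clock bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockbias)
```

## The model

An epigenetic clock predicts age from methylation beta values
$x_{ij} \in [0,1]$ (probe $j$, sample $i$) as a calibrated linear score

$$m_i = \beta_0 + \sum_j \beta_j x_{ij}, \qquad
  \widehat{\mathrm{age}}_i = F^{-1}(m_i),$$

where $F$ is either the identity (blood-style clocks, score already in
years) or the anchored log-linear transform with anchor $A$ (years):

$$F(a) = \begin{cases}\log(a+1) - \log(A+1) & a \le A\\
 (a - A)/(A+1) & a > A\end{cases}$$

$F$ is continuous, strictly increasing and zero at the anchor; its
inverse is $(A+1)e^y - 1$ for $y \le 0$ and $(A+1)y + A$ for $y > 0$.
We fix $A = 20$ years for the multi-tissue-style calibration — the
conventional end-of-development age used by such clocks — but it is a
per-clock field, not a constant. Negative predicted ages (possible when
$y < -\log(A+1)$) are *returned and flagged*, never clipped: a clipped
pathology is an invisible pathology, and surfacing calibration failure
is this package's purpose.

## What the audit measures

**Calibration slope.** OLS of predicted on actual age; an unbiased clock
gives slope 1. We report a two-sided $t$-test of $H_0\colon$ slope $= 1$.
For mathematically exact fits the standard error is 0 and the p-value is
defined as 1 when the line *is* the identity and 0 otherwise.

**Bland-Altman agreement.** Bias = mean of $d_i = \widehat{a}_i - a_i$,
limits at bias $\pm 1.96\,\mathrm{sd}(d)$ with the sample ($n-1$) SD and
the 1.96 normal multiplier exactly (not a $t$ quantile) — the
conventional 95% band under which ~5% of purely random errors fall
outside. Two trend slopes of $d$ are computed: against chronological age
(the headline age-dependence diagnostic; algebraically equal to
calibration slope − 1) and against the pairwise mean (the classical
abscissa). Both are provided because published mean-difference panels
are drawn against either axis.

**Age-binned bias** uses half-open bins $[lo, hi)$; samples outside all
bins are excluded and counted, empty bins are flagged `NA` rather than
dropped.

**Per-locus analytics.** The influence of probe $j$ is
$|\beta_j| / \mathrm{CV}_j$ with $\mathrm{CV}_j = s_j/\bar{x}_j$ over
raw betas (sample SD, arithmetic mean). CV is scale-free, so influence
responds to a probe's *relative* dispersion. Probes with
$\bar{x}_j < 10^{-6}$ get influence `NA` rather than infinity — the
behaviour near zero mean is not otherwise well defined. Ties in the
top-$k$ ranking break by lexicographic probe id so output is
deterministic. Per-probe age slopes are simple OLS of beta on age, no
covariates. A probe is a *saturation candidate* when its mean beta is at
or beyond a boundary threshold (defaults 0.8 / 0.2) **and** its clock
weight pushes it further toward that boundary: such loci have flattened
age responses and stop contributing age signal in the elderly.

**Age-acceleration definitions.** Three non-interchangeable definitions
circulate: $\Delta$-age (DNAm age − chronological age), residuals of
DNAm age regressed on chronological age (optionally plus covariates,
e.g. sex or user-supplied cell proportions — how we represent the
intrinsic/extrinsic variants, since no cell-count reference is bundled),
and the control-referenced form (deviation from a regression fitted on
controls only; case samples never influence the reference line, and when
a sample is ambiguous the case label wins). Under a biased clock
$\Delta$-age inherits the age trend; residuals are orthogonal to age by
construction *on the fitted set*. Both are exposed precisely so the
confounding contrast can be demonstrated.

**Association tests.** Acceleration is the response, the phenotype the
numeric predictor (ordinal stages coded 0–6 numerically — single slope
coefficients imply numeric coding), optionally with age as covariate.
Orientation can matter for interpretation; the acceleration-as-response
form matches how such tables are conventionally reported.

## The synthetic cohort generator

`simulate_cohort()` draws
$\beta_{ij} = \mathrm{logistic}(\alpha_j + \gamma_j a_i + \epsilon_{ij})$,
$\epsilon_{ij} \sim N(0, \sigma_j^2)$. The logistic link — rather than
hard clipping — keeps every beta strictly inside $(0,1)$ and produces
smooth, differentiable compression near the bounds, which is the
saturation mechanism under audit. Defaults (chosen once as a realistic
elderly-cohort caricature, stated here with units):

- 150 training samples uniform on 20–60 years, 150 test samples on
  60–100 years: a young-skewed training set evaluated in old age.
- 100 loci, 60 informative. Informative loci draw $|\gamma_j|$ uniform
  on 0.04–0.08 logit units/year with random sign, and a young-edge logit
  of magnitude 0.5–1.5 oriented so the locus traverses its quasi-linear
  band during the training years and its saturating band after ~60 —
  i.e. mid-range betas in the young, boundary-approaching betas in the
  old. Flat loci have baseline logits on $(-3, 3)$.
- Per-locus noise SD uniform on 0.15–0.35 logit units, roughly 4–9% beta
  SD mid-range — typical array-scale probe noise.
- Phenotype: latent $\kappa a_i + \eta_i$ with $\kappa = 0.08$ per year
  and $\eta \sim N(0,1)$, discretized onto 7 levels (a Braak-like 0–6
  scale) by equal-width bins over the realized range. This yields an
  age–phenotype correlation around 0.7, strong but not deterministic.
  Crucially the phenotype is generated **from age only**: it is
  conditionally independent of methylation given age, so any
  acceleration association it shows is spurious by construction.

Reproducibility: the truth table (locus parameters) and the cohort draw
use two fixed sub-streams derived from the config seed (`seed` and
`seed + 1`), so the locus parameters can be regenerated without
redrawing samples; identical config + seed gives bit-identical output.

What the generator does *not* emulate: array chemistry (intensities,
detection p-values), batch effects, cell-composition mixtures,
tissue-specific trajectories, or 5hmC contamination. Passing tests
therefore demonstrate the *mechanism* — bounded trajectories compress
age signal and bias downstream association tests — not numerical
agreement with any particular real cohort.

## The demonstration clock

`train_demo_clock()` fits ridge regression of $F(a_i)$ on the training
betas with centred predictors and an unpenalized intercept,
$(X_c^\top X_c + \lambda I)b = X_c^\top y_c$. Ridge rather than elastic
net: closed-form, dependency-light, and entirely sufficient to reproduce
the saturation mechanism; no claim of replicating any published training
protocol. $\lambda = 0$ is exact OLS and errors on rank-deficient
designs with advice to use $\lambda > 0$ (noiseless logistic
trajectories become numerically collinear beyond a handful of loci —
a useful reminder that the penalty is doing real work). The default
$\lambda = 0.01$ is a light penalty: with ~150 training samples and
~100 mid-range beta predictors the Gram matrix is well conditioned and
predictions are insensitive to $\lambda$ over several orders of
magnitude.

With these defaults the trained clock fits its training range to ~0.4
years RMSE and shows a test-range (60–100 y) calibration slope around
0.3–0.4 with monotonically decreasing age-binned bias — the
underestimation signature, reproduced end to end from a seed.

## The spurious-association experiment

Each repeat simulates a cohort, trains on the young stratum, predicts
the full cohort, forms $\Delta$-age, and regresses it on the phenotype
without and with the age covariate. With defaults, essentially every
repeat is "significant" ($p < 0.05$) without the covariate; with it the
rejection rate returns to the nominal ~5%. Two calibration notes:

- With $\kappa = 0$ (pure-noise phenotype) the age-free test is itself
  correctly calibrated (~5%), confirming that the inflation comes from
  the age correlation, not from the machinery.
- The age-covaried rate can drift slightly above nominal in some seed
  batches (we have observed up to ~0.12 over 50 repeats): $\Delta$-age
  depends on age *nonlinearly* under saturation, so a linear age
  adjustment leaves a residual trace that a strongly age-correlated
  phenotype can pick up. This is a genuine property of linear covariate
  adjustment, not an implementation artefact, and it is mild at these
  settings.

## Numerical and design details

- All OLS fits go through R's standard least-squares machinery; the test
  suite checks every OLS-derived statistic (residual acceleration,
  calibration fit, locus slopes, association fits) against hand-written
  normal-equations oracles at $10^{-8}$.
- Exact fits (zero residual variance) are handled explicitly where a
  p-value would otherwise be 0/0.
- Missing beta cells are tracked per cell and never imputed at read
  time; imputation is an explicit prediction policy (`impute_mean` by
  default, matching common practice; the applied policy is recorded in
  the result).
- Beta matrices default to probes-in-rows; metadata/beta alignment
  restricts to shared sample ids in sorted order, making it
  order-independent and idempotent.
- CSV coefficient tables use the conventional supplementary-table
  dialect (`probe_id`, `coefficient`, `"(Intercept)"` row) so published
  tables drop in unmodified. Calibration is not serialized in that
  dialect; builtins attach it by name, file sources take it as an
  argument.
- The bundled clock tables are synthetic stand-ins reproducing the
  documented structure of the two published clocks (probe counts 353 and
  71, 6 shared probes, absolute-coefficient range 5.9e-6 to 3.07, named
  high-influence probe ids); the published coefficient values themselves
  are third-party supplementary data and are not redistributed.
- CLI outputs print numerics at fixed 6 decimals with deterministic row
  ordering, so identical invocations are byte-identical and diffable;
  every run writes a JSON manifest (command, parameters, input digests,
  package version, timestamp, seed).
- Problem sizes used by the shipped checks — 300-sample cohorts, 100
  loci, 50 repeats/seeds, a 10,000-draw Bland-Altman Monte Carlo — were
  chosen to make Monte-Carlo fractions stable at the thresholds tested
  while keeping a full run in seconds on a laptop.

## Limitations

- Real-data reproduction of published cohort analyses requires the
  original GEO series and the published coefficient tables; this package
  ships neither, only the machinery to analyse them once supplied.
- Normalization (dasen/BMIQ or clock-specific variants) is out of scope:
  inputs are assumed to be normalized beta values. Different upstream
  normalizations will shift absolute DNAm ages by a few years.
- No cell-type deconvolution is bundled; intrinsic/extrinsic
  acceleration variants are available only as residual acceleration with
  user-supplied cell-proportion covariates.
- Probe identifiers are opaque strings; no array-manifest lookup is
  performed.
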