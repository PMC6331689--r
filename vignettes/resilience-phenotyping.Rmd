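---
title: "Resilience phenotyping from daily feed intake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience phenotyping from daily feed intake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilipig)
```

## The problem

Disease resilience — an animal's ability to keep performing under infection
and other stressors — is hard to select for because direct health records
are sparse, noisy and censored. Electronic feeders change that: a
grow-finish pig visits its feeder many times a day, and illness shows up
within a day or two as depressed feed intake (FI) and less time spent at
the feeder (duration, DUR). This package derives, from per-animal daily FI
and duration records, four resilience phenotypes and validates them against
mortality and medical-treatment records, then estimates their genetic
parameters with animal models.

The four phenotypes are:

* **RMSE_FI**, **RMSE_DUR** — within-animal day-to-day variability: fit an
  ordinary-least-squares line of the daily value on age *within* each
  animal and take the root mean square of its residuals,
  $\sqrt{\mathrm{SSE}/n}$. A resilient pig tracks its own trend tightly; a
  pig hit by disease swings around it.
* **QR_FI**, **QR_DUR** — the proportion of *off-feed days*: fit one
  population-level quantile-regression line at level $\tau = 0.05$ of the
  daily value on age, pooling all eligible animals across batches, and
  count, per animal, the fraction of its days falling strictly below the
  line. This asks "how often was this pig among the worst 5% of
  animal-days for its age?"

Validation traits are mortality (0/1), number of individual treatments to
slaughter (TRT), and the treatment rate standardised to 180 days,
$\mathrm{TRT180} = 180\,\cdot\,\mathrm{count}/\mathrm{last\ alive\ age}$,
recorded for animals reaching 65 days of age. Production traits (nursery
and finishing ADG, ADFI, FCR, residual feed intake, carcass weight,
dressing proportion, backfat, loin depth and polynomial-predicted lean
yield) complete the phenotype table.

## Record cleaning

Daily totals above 5 kg of feed are implausible for a grow-finish pig and
are set to missing; the rule is *strictly greater than*, so an exact 5.00
survives. Missing values (from outages or capping) are filled by a 5-day
rolling average within animal. Two choices here were genuinely open and are
pinned as follows:

* **Window orientation.** The window is centred (±2 days). A trailing
  window cannot fill the second day of a two-day gap from both sides,
  while the centred window handles adjacent missing days naturally. A
  `sides = "trailing"` switch exists for sensitivity analysis.
* **Fill source.** Gaps are filled from *originally observed* neighbours
  only, in a single pass. Imputed values never feed later imputations, so
  the result is independent of fill order and the operation is idempotent.
  Days with no observed neighbour within the window stay missing.

Animals need at least 60 non-missing FI days to receive RMSE/QR phenotypes;
without the floor, pigs dying early in finishing contribute artificially
smooth records and masquerade as highly resilient. Imputed days count
toward the floor by default (`count_imputed = FALSE` reverses this; the
choice moves only a handful of animals at realistic missingness).

## The quantile line as a linear program

The 5% line minimises the pinball loss
$\sum_i \rho_\tau(y_i - a - b\,x_i)$ with
$\rho_\tau(u) = u(\tau - \mathbf{1}[u<0])$. The loss is piecewise linear
and convex, and some optimal line interpolates two data points (a basic
solution of the equivalent LP). The solver exploits this: for small inputs
it enumerates all pair-defined slopes exactly; for large inputs it
minimises the convex slope profile
$f(b) = \min_a \sum_i \rho_\tau(y_i - a - b x_i)$ — the inner minimiser
being an order-statistic quantile of the detrended values — and then
polishes to an exact kink by enumerating pair slopes among the 40 points
nearest the provisional line. The fitted intercept is always an order
statistic of the residuals in original units, which guarantees the
coverage bracket
$\#\{\text{strictly below}\} \le \tau n \le \#\{\text{below or on}\}$
exactly. Ties sit on the line and count as on-feed. The line is fitted
once per analysis on the pooled days of all eligible animals; it is not
refitted per batch, and coefficient ties between alternative optimal basic
solutions are resolved by comparing losses, never coefficients.

Internally the response is rescaled to unit variance before the search and
the slope mapped back, which makes the fit exactly equivariant under
rescaling of the response and keeps QR proportions invariant when intake
units change.

## Growth curves and gains

Body weights arrive roughly every three weeks, so daily weights are
interpolated with LOESS (tricube kernel, span 0.75, local degree 2, no
robustness iterations, exact "direct" surface) per animal, evaluated at
every integer age in the observed range. Extrapolation is forbidden;
phases are clipped to the curve range. Animals with fewer than four
weights — mostly early deaths — fall back to piecewise-linear
interpolation and are flagged, since a local quadratic is under-determined
there. Nursery ADG is the OLS slope of predicted daily weight on age from
quarantine entry to the first FI day; finishing ADG from the first to the
last FI day. FCR uses the LOESS-predicted weights at the phase endpoints
rather than raw weighings, because endpoint weighings rarely align with
phase boundaries and dying animals are weighed at irregular, informative
times.

## Production traits

ADFI is the arithmetic mean of non-missing finishing-day intakes; FCR is
total feed over endpoint weight gain (non-positive gain yields a missing
value with a warning). Residual feed intake is the residual of ADFI on
batch, finishing start age and pen plus average finisher body weight,
finishing ADG and ultrasound backfat. Metabolic scaling
($\mathrm{weight}^{0.75}$) of the weight covariate is the default, with
plain weight available by `metabolic = FALSE`; the averaging of daily
LOESS weights over the finishing window defines "average body weight".
Lean yield evaluates the Québec carcass polynomial
$68.1863 - 0.7833\,\mathrm{CBF} + 0.0689\,\mathrm{CLD} +
0.008\,\mathrm{CBF}^2 - 0.0002\,\mathrm{CLD}^2 +
0.0006\,\mathrm{CBF}\cdot\mathrm{CLD}$ exactly; it is dominated by backfat
and decreases monotonically in CBF over observed carcass ranges.

## Animal models

Variance components come from restricted maximum likelihood under
$y = Xb + a + e$, $a \sim N(0, K\sigma^2_a)$, $e \sim N(0, I\sigma^2_e)$,
with $K$ a pedigree (tabular method), genomic (VanRaden,
$ZZ'/\sum 2p_jq_j$) or single-step blended H matrix. Mortality is analysed
as a linear 0/1 trait. Fixed effects are batch and quarantine entry age
for mortality/treatment traits, and batch, finishing start age and pen for
finishing traits; factors enter with reference-level contrasts, ages as
linear covariates, no interactions. Litter effects are not modelled.

Two engine choices matter:

* **Univariate.** After one eigendecomposition of $K$ the restricted
  likelihood profiles down to a 1-D search over
  $\lambda = \sigma^2_a/\sigma^2_e$, solved by golden-section/parabolic
  minimisation to tolerance $10^{-9}$; the optimum is exact for practical
  purposes, and boundary solutions ($\sigma^2_a \to 0$) are detected and
  flagged. Standard errors come from the inverse numerical observed
  information, with the delta method for $h^2$.
* **Bivariate.** Both traits share one fixed-effects design and one
  relationship matrix, so rotating by the eigenvectors of $K$ decouples
  the likelihood into independent 2×2 blocks per eigenvalue; each
  evaluation is then $O(n)$. The 2×2 genetic and residual covariance
  matrices are parameterised by log-Cholesky factors, keeping them
  positive definite and $|r_g| \le 1$ throughout, and the likelihood is
  maximised directly by Nelder-Mead (two restarts, relative tolerance
  $10^{-12}$) from univariate starting values. Direct maximisation of the
  canonical form was chosen over EM-with-AI-acceleration because each
  evaluation is exact and linear in $n$, so acceleration buys nothing at
  these problem sizes. The bivariate model uses animals with both traits
  observed; with per-trait missingness the canonical factorisation no
  longer applies, and the discarded rows are few in the designs this
  package targets. A non-decreasing best-so-far objective trace is stored
  for monotonicity checks.

The H matrix follows common single-step practice: G is rescaled so its
mean diagonal and off-diagonal match the genotyped block of A, blended
with weight 0.95 on the genomic side, and the weight is lowered stepwise
with a warning in the (rare) non-PSD case.

## The cohort simulator

Every downstream stage is validated on simulated cohorts, so the generator
is first-class, tested code. Its defaults describe the study conditions
the analysis is designed for: 21 batches of 64 pigs (1,344 animals), a
60-sire × 4-dams-per-sire half-sib structure, finishing between 70 and 181
days of age, feed intake rising linearly from 1.4 kg/day at about 15 g/day
per day of age (finishing mean ≈ 2.2 kg/day), duration coupled to intake
through an animal-specific intake rate, and illness episodes arriving as a
Poisson process (1.2 per 100 days at average susceptibility) whose depth
and frequency scale with a heritable latent susceptibility. Episode
severity — plateau depth × length, in lost feed-days — triggers an
individual treatment above 2.5 and death above 7.08; the mortality
threshold was calibrated once, by bisection on the default configuration,
so the default cohort realises the intended ≈26% mortality, and is not a
tuning dial. Latent heritabilities default to 0.3 with genetic
correlations (susceptibility, appetite, growth) of −0.3/−0.4/+0.4, the
structure needed for off-feed phenotypes to correlate genetically with
mortality and growth.

Decisions where the biology gives no unique answer, recorded here as the
package's own choices:

* **Within-episode shape.** Intake drops along a rectangular plateau with
  2-day linear onset and recovery ramps. Real episodes vary; the
  rectangle-with-ramps shape reproduces the characteristic dip-and-recover
  look of off-feed events without extra parameters.
* **Episode monotonicity by construction.** Each animal pre-draws a fixed
  pool of episode attributes and takes the first $N$ of them, with $N$ an
  inverse-CDF Poisson draw; raising the rate can only append episodes, so
  realised off-feed days are monotone in the configured rate under a fixed
  seed.
* **Reproducibility.** Every animal runs in its own RNG substream keyed by
  a stable index, so cohorts are byte-identical across runs and invariant
  to animal ordering.
* **Pedigree.** A full sire+dam half-sib design (maskable to dam-only)
  keeps REML parameter recovery well-posed; a dam-only pedigree identifies
  variance components much more weakly.
* **Genotypes** are gene-dropped haplotypes from Hardy–Weinberg founders
  with free recombination, so genomic relationships match pedigree
  expectations without modelling linkage.

What the simulator does *not* emulate: pathogen-specific dynamics,
pen-level transmission, seasonal diet changes (a sinusoidal batch-severity
option exists, default off), visit-level feeder noise, and genotyping
error. Passing tests on simulated cohorts therefore demonstrate that the
pipeline recovers the parameters of *this* generative model at these
sample sizes — not that real barn data are this clean.

## Numerical choices and degenerate inputs

* RMSE uses $\sqrt{\mathrm{SSE}/n}$ (a `denominator = "n-2"` option
  exists); at the 60-day floor the difference is below 2%.
* Off-feed classification treats days within $10^{-8}$ (relative) of the
  line as on the line, so floating-point ties never flip a day's class.
* Quantile lines require two distinct ages; animals with fewer than three
  usable days get no RMSE; phases shorter than two days give no ADG;
  non-positive FCR gain yields a missing value, never an infinity.
* Rank-deficient fixed-effect designs drop aliased columns (logged), so
  confounded batches cannot crash a fit.
* REML boundary estimates are pinned at zero and flagged; bivariate
  non-convergence is reported, mirroring how such entries are flagged in
  practice.

## Problem sizes used in validation

The shipped tests exercise: record cleaning and trait arithmetic on exact
hand-computed fixtures; quantile fits against brute-force pair enumeration
at up to 12 points and dual solver paths at 300; LOESS against a pointwise
tricube-weighted WLS oracle; pedigree A against 10,000-replicate gene
drops; REML against a dense grid-search restricted likelihood at $n = 30$
and parameter recovery at $n = 2{,}000$ (200 sires × 10 offspring, 10
seeds, univariate $h^2 = 0.25$ and bivariate $r_g = 0.6$); and a full
pipeline run on a 2,048-pig cohort with heritable susceptibility, which
yields a strictly positive heritability for the off-feed proportion and a
positive genetic correlation with mortality. These sizes were chosen to
make sampling noise small relative to the tested effects while keeping
the whole suite runnable on a laptop.

## Known limitations

* The bivariate engine requires complete cases and a shared fixed-effects
  design across the two traits.
* QR and RMSE phenotypes enter the models untransformed; both are bounded
  or skewed, and a logit/log transform may be preferable at higher
  off-feed prevalence.
* The H-matrix path is exercised at desk scale only; very large genotype
  sets need sparse-inverse machinery this package does not provide.
* Threshold (liability) models for mortality are deliberately absent;
  linear-model heritabilities of 0/1 traits are scale-dependent.
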