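---
title: "Deterministic and stochastic components of age-dependent methylation variability"
author: "methvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic and stochastic components of age-dependent methylation variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## The problem

Blood DNA methylation measured on Illumina 450k arrays changes with age,
and for many CpG probes the *spread* across people grows with age even
faster than the mean shifts. Two very different dynamical pictures produce
the same cross-sectional fan: (a) individuals follow smooth personal
trajectories with heterogeneous slopes that diverge over decades
(deterministic heterogeneity), or (b) each individual performs a biased
random walk whose fluctuations accumulate (stochastic noise).
Cross-sectional data cannot distinguish them; longitudinal data can.
`methvar` implements the full analysis chain: selection of age-variable
probes (aVMPs), a signal-to-noise-ratio (SNR) decomposition of the
variability on longitudinal and twin data, inference of the functional law
linking the variance to the methylation level, and discrimination of
linear, power-law and exponential age trends of the level itself.

## Variability and aVMP selection

For probe $i$, the pointwise variability at a sample with age $a$ is
$\sigma_i^2 = (\beta_i - \langle\beta_i\rangle)^2$, where
$\langle\beta_i\rangle$ is the mean over a sliding 10-year age window
(all samples within $\pm 5$ years, closed interval, evaluated at every
sample's own age; edge windows are truncated). Age dependence of any
quantity is always assessed the same way: OLS on age with the two-sided
t-test on the slope. aVMPs are probes whose $\sigma_i^2$-on-age
regression is significant after Benjamini–Hochberg correction in *both*
cohorts, at adjusted $p < 0.001$ in the wide-age-span cross-sectional
cohort and $p < 0.05$ in the longitudinal cohort (its narrower age span
justifies a milder gate). BH is applied within each (dataset, sex)
stratum; males and females are analysed separately throughout.

## The SNR decomposition

Three signal-to-noise statistics are computed per probe on the
longitudinal cohort:

* **Trajectories.** For each individual with at least three visits at
  distinct ages, a line is fitted through their values;
  $\mathrm{SNR}_z = \frac{1}{M}\sum_j \beta_{r,j}/\sigma_j$ with
  $\sigma_j = |\beta_j - \beta_{r,j}|$, averaged (unweighted) over
  individuals. Two-visit individuals are skipped because a line through
  two points has no residual.
* **Twin pairs.** Same-sex pairs only. Visit series are synchronized:
  where one twin lacks a measurement at an age strictly inside its
  observed span, its value is linearly interpolated between the two
  bracketing visits; no extrapolation. At each synchronized point the
  signal is the pair mean and the deviation the half absolute difference;
  pairs need at least two synchronized points.
* **Cloud.** All points pooled with longitudinal identity ignored; the
  signal is the 10-year window mean and the deviation the absolute
  difference from it.

Zero deviations are handled by one policy everywhere: points with
deviation below `epsilon` ($10^{-8}$) are excluded from the mean of
ratios; a unit whose points are all excluded (an exact fit) maps to the
cap (`snr_cap`, $10^6$), and finite means are clamped to the cap. This
keeps the statistic finite and monotone in the noise level.

The key quantifier is
$\log_{10}(\mathrm{SNR}^{trajectories}/\mathrm{SNR}^{cloud})$: positive
values mean individual trajectories are much cleaner than the
cross-sectional cloud, so the spread comes from heterogeneity between
people (**deterministic**); values at or below zero mean within-person
fluctuation is the dominant source (**stochastic**). The call uses the
strict boundary at ratio 1.

### What the boundary can and cannot show

A structural property of this statistic is worth stating openly, because
it shapes what synthetic benchmarks can demonstrate. Fitting a line to
$M$ points deflates residuals by roughly $\sqrt{(M-2)/M}$ relative to
deviations from a window mean, so with $M = 4$ visits *any* generator
with independent noise has a log-ratio floor slightly above zero: even a
pure random walk with no heterogeneity lands at a small positive median
($\approx +0.1$ at the default settings), and only a minority of
random-walk probes fall below the strict boundary. The synthetic
benchmark therefore shows that the two mechanisms *separate cleanly*
(divergence probes sit far to the right of random-walk probes, and the
random-walk median is near zero) rather than that the strict boundary
recovers the stochastic label at high sensitivity. On real data,
additional deviation sources that the generator deliberately omits
(technical noise shared across a chip, outlier visits) move probes across
the boundary in both directions.

## Variance–mean scaling laws

For aDMPs — probes whose mean methylation itself trends with age
(absolute slope above $0.001$ per year, i.e. at least $0.1$ beta per
century, *and* $R^2$ above the 99th percentile of the per-sex $R^2$
distribution, linear-interpolation percentile) — the aDaVMP subset
additionally has BH-adjusted variance trends at $p < 0.001$. Each aDaVMP
is normalised two ways:
$CV^2 = \sigma^2/\langle\beta\rangle^2$ and the Fano factor
$F = \sigma^2/\langle\beta\rangle$. When level and variability trend in
opposite directions the demethylated fraction $1-\langle\beta\rangle$
replaces $\langle\beta\rangle$ (a shrinking methylated fraction with
growing noise is naturally scaled by what remains to lose). If the
normalisation removes the age dependence (BH-adjusted $p \ge 0.001$), the
corresponding law is inferred: age-flat $CV^2$ implies
$\sigma^2 \sim \beta^2$, age-flat $F$ implies $\sigma^2 \sim \beta$. If
both normalisations stay age-dependent the probe is left unresolved
(`NA`). If both are flat the quadratic law wins (it is tested first and
dominates empirically); such ties are flagged in the output.

## Linear, power-law and exponential trends

Three models are fitted per aDMP: $\beta = k\,a + b$;
$\ln\beta = \alpha \ln a + p$ (power law $\hat\beta \sim a^\alpha$); and
$\ln\beta = \gamma a + q$ (exponential). The log-space fits are least
squares in the transformed axes — no bias correction is applied — but all
three are scored on the original beta scale by $R^2 = 1 - RSS/TSS$, so
back-transformed $R^2$ can be negative. Betas are floored at $10^{-6}$
before logs (floored values are retained so all models see the same
points); ages must be strictly positive.

Both the power and the exponential model are also fitted to the
complementary value $1-\beta$; if the best nonlinear $R^2$ on $1-\beta$
is at least 5% higher (multiplicative, $R^2 \ge 1.05\,R^2_{ref}$; an
absolute margin of $0.05$ is used as fallback when the reference is
non-positive) the complement orientation is adopted. The class is then:
strongly nonlinear (power or exponential, by the larger $R^2$, ties to
power) when the best nonlinear $R^2$ beats the linear one by 5%;
`weak_nonlinear` when it lies within $\pm 5\%$; `linear` otherwise.

The 5% rule has a geometric consequence on well-fit probes: once the
linear $R^2$ exceeds $1/1.05 \approx 0.952$, *no* model can be 5% higher,
so gently curved trends (e.g. $a^{0.3}$ over ages 14–94, whose linear
$R^2$ is $\approx 0.98$) are classified `weak_nonlinear` no matter how
little noise there is, even though the exponent itself is recovered to
three decimals. Strong nonlinear calls are reserved for probes whose
curvature is large enough to pull the linear fit below that threshold.

## Cell-composition adjustment

When blood cell fractions (CD8T, CD4T, NK, B, granulocytes) are
supplied, each probe is regressed on the five fractions plus an intercept
(per sex), and the residuals are shifted up by the absolute value of the
smallest residual of that probe/stratum, so adjusted values are
non-negative (the shift is per probe within each stratum, matching the
stratified regression). Collinear covariate columns are dropped by
rank-revealing QR instead of erroring, since synthetic fractions can be
degenerate. No additional epsilon floor is applied at this stage; the
$10^{-6}$ floor of the log fits covers downstream positivity.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the exact
structures the inference assumes so that every stage can be checked
against ground truth.

* **Designs.** Cross-sectional: one visit per individual at a uniform
  random age (default span 14–94 years, emulating a wide-span population
  cohort). Longitudinal: fixed visit spacing (default 3 years) with
  baseline ages drawn so the schedule fits the span (default 48–98,
  emulating an elderly twin cohort). A configurable fraction of
  individuals form same-sex twin pairs sharing sex and visit ages.
* **Trends.** Linear, power, exponential or constant laws, applied to
  $\beta$ or to $1-\beta$. Mean trajectories are validated to stay within
  $[0,1]$ over the configured span; generated betas are clipped to
  $[10^{-6}, 1-10^{-6}]$ so log fits are always defined.
* **Divergence mechanism.** One slope perturbation per individual
  (s.d. `divergence_sd`, default 0.002 per year), anchored at the
  cohort's minimum age so trajectories fan out from a common origin and
  the cross-sectional variance grows quadratically with elapsed age.
  Twins share the perturbation up to an intra-pair jitter of 10% of
  `divergence_sd`; zero jitter would collapse the twin SNR onto the
  trajectory SNR, while independent draws would collapse it onto the
  cloud SNR — the intermediate value reproduces the observed ordering
  trajectories > twins > cloud.
* **Random-walk mechanism.** From the individual's first visit,
  $u(t+\Delta) = u(t) + \text{trend increment} + \text{step}$ with step
  s.d. `step_sd`$\cdot\sqrt{\Delta}$ (default 0.02 per $\sqrt{\text{yr}}$);
  the drift equals the trend's increment so both mechanisms share the
  same population mean and differ only in how variability arises. In a
  cross-sectional design there is no within-individual walk to simulate,
  so the marginal displacement $N(0,$ `step_sd`$^2 (a - a_{min}))$ of a
  walk from the cohort's minimum age is used, which preserves the
  linear-in-age variance signature.
* **Noise scalings.** Visit-level noise with s.d. constant
  (`additive_constant`), proportional to the level (`cv_constant`,
  giving $\sigma^2 \sim \beta^2$), to its square root (`fano_constant`,
  $\sigma^2 \sim \beta$) or to the 3/2 power (`cubic`,
  $\sigma^2 \sim \beta^3$ — a law neither normalisation removes, used to
  test the unresolved group).

### Study conditions frozen as defaults

Two probe panels recur in the tests and the acceptance script, and their
parameters are the package's fixed study conditions, chosen for realism
once and not tuned afterwards:

* the **longitudinal D×S panel**: mean trend $0.4 + 0.001\,a$ (a weak
  mean drift — aVMPs are selected on variance, not mean, so the typical
  aVMP is not a strong aDMP), additive visit noise 0.005, divergence s.d.
  0.002/yr or walk step 0.02; 150 individuals × 4 visits;
* the **cross-sectional scaling panel**: mean trend $0.15 + 0.005\,a$
  (a strong aDMP-like trend, since aDaVMPs pass the slope and $R^2$
  gates), relative noise magnitude 0.08 (CV of 8%, typical of variable
  blood CpGs), 700 samples of one sex.

The generator emulates the statistical skeleton of array data — it does
not simulate chip chemistry, batch effects, detection failures, shared
technical noise or genomic coordinates, so passing tests demonstrate the
correctness and power of the statistical machinery under the stated
mechanisms, not robustness to array artefacts.

## Numerical choices

* Exact fits and constant responses: a response that is constant to
  machine precision gets slope 0, $R^2 = 0$, $p = 1$; a non-flat exact
  fit gets $p = 0$.
* Window membership uses closed intervals; ties at the boundary are
  inside.
* The odds ratio reported by the enrichment stage is the sample
  cross-product $(ad)/(bc)$ (`Inf` or `NA` in degenerate tables); the
  p-value is the exact two-sided (minimum-likelihood) test. The
  background is the analysed universe minus the probe list.
* Probe-level SNR means are unweighted over individuals and pairs,
  regardless of how many points each contributes.
* All randomness flows through the single seed in the cohort
  configuration; identical configurations are bit-identical.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
400-probe longitudinal cohorts (150 × 4) for the D×S benchmark, 300-probe
cross-sectional cohorts (n = 700) for the scaling and trend benchmarks,
and one 5000-probe end-to-end pipeline run over a paired cross-sectional
(n = 700) and longitudinal (150 × 4, 40 twin pairs) cohort. These sizes
give stable recovery rates while keeping a full run in the minutes range
on a single core.

## Known limitations

* The strict ratio boundary under-calls stochastic probes at small $M$
  (see above); a bias-aware boundary (e.g. at the $\sqrt{M/(M-2)}$
  deflation) would be a natural extension but is deliberately not the
  default, to keep the published decision rule.
* The 5% multiplicative $R^2$ rule cannot flag strong nonlinearity on
  probes whose linear $R^2$ exceeds $\approx 0.95$.
* Missing beta values are rejected, not imputed; upstream QC and
  normalisation are out of scope and assumed done.
* The twin model treats pairs as exchangeable and ignores zygosity.
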