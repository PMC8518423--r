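---
title: "How many known-age individuals does an epigenetic clock need?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many known-age individuals does an epigenetic clock need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenetic clocks predict chronological age from DNA methylation: a sparse
linear model over CpG beta values (methylation fractions in $[0,1]$),
calibrated on individuals of known age. In wildlife work, known-age animals
are the scarce resource, so the question this package answers is operational:
**given a candidate calibration population of size $n$, how accurate and how
stable will the resulting clock be — and at what $n$ does adding animals stop
helping?**

The approach is Monte-Carlo resampling of a large reference cohort. For each
calibration size $n$ on a grid, many random subsamples of size $n$ are drawn;
each is split 70/30 (preserving the sex ratio), an elastic-net age model is
fitted on the training part with 10-fold cross-validation, and test-set
performance is recorded. Two complementary analyses sit on top:

1. **Corridor / point of stability.** The Pearson correlation between
   predicted and true age rises with $n$ towards a plateau $r_{\mathrm{true}}$.
   The corridor of stability of half-width $w$ is
   $[r_{\mathrm{true}} - w,\ \min(1, r_{\mathrm{true}} + w)]$; the point of
   stability (POS) at level $q$ is the smallest $n$ from which the central
   $q\%$ interval of the iteration correlations lies inside the corridor at
   every larger $n$ — the sample size at which the clock's accuracy is not
   just high on average but reliably so.
2. **Sliding-window age-range removal.** Samples are ordered by age and a
   contiguous block ($10\%$–$90\%$ of the cohort, sliding one position at a
   time) is removed; the clock is trained on the remainder and evaluated on
   the removed block. The MAE increase over the full-data baseline, in units
   of the baseline's SD (Cohen's $d$), quantifies how far the clock
   extrapolates into age ranges it never saw.

## The model unit

One Monte-Carlo unit is: sex-stratified 70/30 split; fit of

$$\min_{\beta_0, \beta}\ \frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
  + \lambda\Big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big)$$

with $\alpha = 0.5$ over a 100-point log-spaced $\lambda$ path down to
$10^{-3}\lambda_{\max}$, predictors standardised internally and coefficients
reported on the beta scale (the glmnet convention used throughout the
epigenetic-clock literature); $\lambda$ chosen at minimum mean 10-fold CV
error. Evaluation reports the test-set Pearson $r$, the mean absolute error
(MAE, in age units), the relative MAE as a percent of the oldest individual
in the reference cohort, and the number of CpGs the model selected.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | L1/L2 mixing; 0.5 is the standard clock setting |
| `cv_folds` | 10 | CV folds for the $\lambda$ choice (minimum 3, a solver constraint) |
| `train_fraction` | 0.7 | training share of each subsample, sex-stratified |
| `iterations` | 100 | Monte-Carlo repeats per grid point (20 at desk scale) |
| widths $w$ | 0.10/0.15/0.20 | corridor half-widths (Cohen's small/medium/large) |
| percentiles | 80/90/95 | envelope levels for the POS criterion |
| $d$ levels | 0.20/0.50/0.80 | Cohen's $d$ compliance levels for window removal |
| `tail_points` | 10 | grid tail averaged into $r_{\mathrm{true}}$ |

## Design choices where the design was open

**$\lambda$ rule.** Minimum mean CV error (`lambda_rule = "min"`), because the
analyses score accuracy (MAE, $r$), which the 1-SE rule deliberately trades
away; `"1se"` is available as a switch.

**POS estimator.** With independent iterations at each $n$ (rather than one
growing sample trajectory), "enters and does not leave the corridor" needs an
estimator. The default requires the central $q\%$ percentile envelope at
every $n' \ge n$ to sit inside the corridor; a `method = "fraction"`
alternative (at least $q\%$ of iterations inside the corridor) is provided
for sensitivity analysis. Percentile (not normal-theory) intervals are used
throughout so the summary band and the POS criterion agree.

**$r_{\mathrm{true}}$.** Mean of `mean_r` over the 10 largest grid points, not
the single largest $n$, to damp Monte-Carlo noise. A plateau diagnostic (tail
slope $> 5\times10^{-4}$ per sample) flags trajectories still rising at the
largest available $n$ — in that case $r_{\mathrm{true}}$ is a lower bound and
POS values are underestimates, the situation small cohorts are in.

**Window evaluation target.** The window analysis trains on all retained
samples and scores MAE **on the removed window**: that is the extrapolation
question, and it is what produces the characteristic U-shape (edge windows
hurt most). A `evaluate_on = "holdout"` switch scores a 30% holdout of the
retained samples instead, for comparison. Compliance is one-sided
($d \le$ level): a model that got *better* after removal never fails.

**Infeasible fractions.** A removal fraction leaving fewer than
`min_retained` (15) samples cannot train a 10-fold CV model; the scan records
it as an all-NA row (the published convention for its table) rather than
aborting, while direct window enumeration errors.

**Stratification arithmetic.** Per-sex training counts use
$\lfloor f \cdot n_{\mathrm{sex}} + 0.5\rfloor$ with a one-sample seeded
adjustment when the global total misses $\mathrm{round}(fN)$; subsamples
preserve the cohort's own sex proportions (not forced 50/50). Ties in the
age ordering are broken by sample id so window positions are reproducible.

**Determinism.** Every Monte-Carlo task seeds its own RNG with a hash of
(base seed, grid coordinates, iteration), so results are independent of
execution order and reproducible bit-for-bit from one base seed.

## The synthetic cohort generator

No public generator existed for joint methylation-age data, so the package
ships one: ages i.i.d. uniform over a range; sexes balanced to within one;
for an age-associated CpG $j$,
$\beta_{ij} = \mathrm{clip}(b_{0j} + s_j \cdot \tilde a_i + \varepsilon_{ij},\ 0,\ 1)$
with $\tilde a_i$ the min-max-normalised age, baseline
$b_{0j} \sim U(0.15, 0.85)$, signed slope magnitude from `slope_range`, and
homoscedastic Gaussian noise on the beta scale; non-associated CpGs omit the
slope term. Optional X-flagged CpGs (constant $+0.2$ male offset) exist only
to exercise the sex-chromosome filter.

The default configuration mirrors the reference human whole-blood cohort in
shape — 394 samples, ages uniform on 16–88 years, balanced sexes — with 50
age-associated CpGs among 1,000. Slopes (0.05–0.10) and noise SD (0.05) were
calibrated analytically so the *achievable* correlation plateaus near 0.95,
the value large human cohorts reach: with independent per-CpG noise the
population $R^2$ is bounded by $S/(1+S)$ where
$S = \sum_j (s_j \,\sigma_{\tilde a}/\sigma_\varepsilon)^2 \approx 9.3$ at
these defaults ($\sigma_{\tilde a} = 1/\sqrt{12}$).

What the generator deliberately does **not** emulate: array error profiles,
batch effects, cell-type heterogeneity, age-dependent noise, correlated CpG
modules, or nonlinear (logarithmic) clock transforms. Passing tests on this
generator therefore demonstrate that the estimators behave correctly under
the assumed linear-signal model, not that any particular POS value transfers
to a real cohort — on real data the plateau, and hence the POS, must be
re-estimated.

## Problem sizes

The package's own analyses and checks run at desk scale: scans use a 394-
sample cohort thinned to 500 CpGs (the same 50 informative ones, so the same
plateau) on a grid of step 10 with 20 iterations per point; window scans use
a 100-sample strong-signal cohort (400 CpGs) at fractions 0.1/0.3 with 5
iterations per window and a 20-iteration baseline. The full protocol — step
1, 100 iterations, all nine fractions, a 100-iteration baseline — is a
flag change in the `analysis/` drivers (roughly 50× the compute). Desk-scale
POS values are noisier than full-protocol ones but reproduce the orderings
that matter: POS shrinks as the corridor widens, grows with the percentile
level, and the strictest setting (w = 0.10, 95%) stabilises far later than
the laxest (w = 0.20, 80%).

## Numerical notes

- Elastic-net convergence threshold is $10^{-10}$ so returned coefficients
  satisfy the KKT stationarity conditions to ~$10^{-4}$ (checked in tests by
  an independent subgradient oracle that accounts for predictor and response
  standardisation).
- Zero-variance CpGs in a training split are dropped before fitting
  (standardisation is undefined for them).
- CV error is averaged per observation (`grouped = FALSE`): at the smallest
  grid sizes 10-fold CV has single-sample folds, where the grouped estimator
  is unavailable; one code path keeps the estimator identical across the grid.
- A test set whose predictions are constant has undefined Pearson $r$; it is
  recorded as NA and excluded from correlation summaries (MAE is unaffected).
- Iteration failures (degenerate subsamples) are recorded; more than 10%
  failures at a grid point aborts the scan.
- Beta values within $10^{-9}$ outside $[0,1]$ are clamped on read; anything
  worse is an error naming the cell.

## Known limitations

- The POS depends on the corridor being anchored at a genuine plateau; for
  cohorts whose trajectory is still rising (flagged by the plateau
  diagnostic) every reported POS is an underestimate.
- Independent per-CpG noise makes many-CpG models slightly stronger than on
  real arrays, where noise is partly shared; desk-scale absolute POS values
  should be read as qualitative.
- The window analysis removes one contiguous age block; real age gaps can be
  non-contiguous, and no weighting scheme for skewed age distributions is
  provided.
- Ages are modelled untransformed; clocks using log-age warps for juveniles
  are out of scope.
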