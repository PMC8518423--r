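# clocksize

**How many known-age individuals does it take to calibrate a DNA-methylation
age estimator?**

Epigenetic clocks — sparse elastic-net models predicting chronological age
from CpG methylation beta values — are increasingly used in wildlife
research, where known-age animals are the limiting resource. `clocksize`
answers the sample-size question by Monte-Carlo resampling of a reference
cohort: for each calibration size *n* it repeatedly subsamples, fits a
sex-stratified 70/30, 10-fold cross-validated elastic net (α = 0.5), and
scores the held-out samples; it then

- estimates the plateau ("true") test-set correlation
  *r*<sub>true</sub> of the performance trajectory,
- finds the **point of stability**: the smallest *n* from which the central
  *q*% interval of iteration correlations enters the corridor
  [*r*<sub>true</sub> − *w*, min(1, *r*<sub>true</sub> + *w*)] and never
  leaves it (widths *w* = 0.10/0.15/0.20, levels 80/90/95%), and
- quantifies **extrapolation error** with a sliding-window age-range removal:
  order samples by age, remove a contiguous 10–90% block (sliding by one),
  train on the rest, score MAE on the removed block, and report the window
  positions whose MAE increase over the full-data baseline stays within
  Cohen's *d* = 0.20/0.50/0.80.

A synthetic methylation–age cohort generator (uniform ages, balanced sexes,
a minority of CpGs drifting linearly with age plus clipped Gaussian noise)
makes the whole pipeline testable without array downloads.

## Worked example

```r
library(clocksize)

# a human-shaped cohort: 394 samples, ages uniform on 16-88, 500 CpGs
# (50 age-informative at an SNR calibrated for a ~0.95 plateau)
sim <- simulate_dataset(simulation_config(n_cpgs = 500, seed = 77))

scan <- run_samplesize_scan(
  sim$dataset,
  scan_config(n_min = 15, n_max = 394, n_step = 10, iterations = 20,
              base_seed = 77))
summarize_scan(scan)[c(1, 10, 38), 1:5]
#>      n    mean_r   r_ci_low r_ci_high  mean_mae
#> 1   15 0.3815127 -0.3538836 0.8234283 15.445980
#> 10 105 0.8862097  0.7723420 0.9425570  7.447280
#> 38 385 0.9371804  0.9197787 0.9527219  5.882371

stability_table(scan)
#> r_true = 0.9345 (tail of 10 points, slope 5.3e-05/sample, plateaued)
#>  width percentile pos_n    r_true plateau_flag
#>   0.10         80   125 0.9344702    plateaued
#>   0.10         90   125 0.9344702    plateaued
#>   0.10         95   135 0.9344702    plateaued
#>   0.15         80    65 0.9344702    plateaued
#>   0.15         90    75 0.9344702    plateaued
#>   0.15         95   125 0.9344702    plateaued
#>   0.20         80    45 0.9344702    plateaued
#>   0.20         90    65 0.9344702    plateaued
#>   0.20         95    65 0.9344702    plateaued
```

Read: with this cohort, test-set correlation climbs from ~0.38 at *n* = 15
to a ~0.93 plateau; a clock becomes *reliably* accurate (within ±0.20 of the
plateau for 80% of random cohorts) at 45 samples, but the strict criterion
(±0.10 at 95%) needs 135 — the same "minimum vs ideal" gap the method is
designed to expose. At full protocol (grid step 1, 100 iterations:
`analysis/02_samplesize_scan.R --step 1 --iterations 100`) the estimates
sharpen accordingly.

The `analysis/` directory holds the numbered drivers for the complete
workflow (simulate → scan → stability table → window removal), each writing
its tables under `results/`.

## Scope notes

The package operates on processed beta matrices (TSV/CSV, gzip supported,
CpG-major or sample-major) with `sample_id`/`age`/`sex` metadata and an
optional CpG→chromosome annotation for sex-chromosome probe removal. Raw
IDAT/bisulfite processing, normalisation, GEO/ArrayExpress downloading and
figure rendering are out of scope.
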