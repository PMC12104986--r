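# sdmaxent

Presence-only species distribution modelling with maximum entropy, for
ecologists who need the full analysis around the model as well: mapping
the present and future range of a sporadic species (the motivating case
is a rare Mediterranean oak) from occurrence records and gridded
environmental predictors.

## What it does

The core is a presence-background MaxEnt model. Landscape cells carry a
Gibbs (log-linear) density over the background sample,

    p(x) = exp( sum_j beta_j f_j(x) ) / Z,

where the features `f_j` are the classic MaxEnt expansions of the raw
predictors — linear (L), quadratic (Q), pairwise products (P), forward and
reverse hinges (H) and step thresholds (T), plus one indicator per class of
each categorical predictor — and the coefficients maximize the L1-penalized
presence log-likelihood with per-feature penalties
`lambda_j = r * base(class_j, m) * sd_j / sqrt(m)` (`r` the regularization
multiplier, `m` the presence count, `base` the published MaxEnt default
tables). Predictions come as the raw density or on the cloglog scale
`1 - exp(-exp(H) * raw)`, whose fixed anchor `1 - 1/e ≈ 0.632` is the value
of a cell expected to hold one individual.

Around the model, the package implements the standard workflow:

- **occurrences** — deduplication to one record per 1-km grid cell and
  protection-status summaries against protected-area polygons;
- **predictors** — resampling heterogeneous rasters to the study grid,
  iterative removal of collinear variables (pairwise |r| > 0.7, highest
  mean |r| removed first, priority variables protected) with a VIF audit;
- **evaluation** — spatial block cross-validation, AUC and its
  training-validation difference, AICc with k = non-zero coefficients, the
  Continuous Boyce Index, and a 50-combination grid search over feature
  classes (L, LQ, LQH, LQHP, LQHPT) and regularization multipliers
  (0.5–5.0);
- **projection** — MTP / P10 / fixed-threshold suitability classes with
  area accounting, climate-scenario projections with range change and
  altitude shifts, and MESS extrapolation surfaces;
- **synthetic data** — a virtual-species generator (correlated smooth
  layers, categorical soil, unimodal truths, presence sampling) so the
  whole pipeline is testable offline.

Rasters are read and written as plain-text ESRI ASCII grids (`.asc`);
occurrences and polygons as CSV/GeoJSON; models as JSON.

## Worked example

```r
library(sdmaxent)

demo <- make_demo(tempfile("demo"), seed = 1)   # virtual species dataset
res  <- run_pipeline(demo$config)               # the full workflow
print(res$tuning)
```

```
MaxEnt tuning: 50 candidates (0 failed)
Top of the AICc ranking:
 rank classes reg_mult n_params  aicc auc_diff    cbi
    1     LQH      2.5       13  3842  0.05616 0.7739
    2   LQHPT      1.0       32  3843  0.10103 0.6836
    3     LQH      4.0       10  3844  0.05123 0.7636
 ...
Selected: LQ, reg_mult 5 (AUC_diff 0.042 +/- 0.032, CBI 0.698 +/- 0.229)
```

Each row is one feature-class / multiplier combination: `aicc` ranks fit
versus complexity on the full data, `auc_diff` (mean over the four spatial
blocks) gauges overfitting — smaller generalizes better — and `cbi` gauges
calibration on the held-out blocks (1 is perfect, 0 random). The selection
minimizes `auc_diff` and maximizes `cbi`, optionally within one
feature-class family; response curves for any candidate come from
`response_curve()` for the final plausibility check by eye.

The run directory then holds the gridded occurrences, the selection report,
the tuning table, the fitted model, threshold and four-class area tables,
e.g.

```
       class area_km2       pct
  Negligible      367       9.0
         Low      937      22.9
    Moderate      910      22.2
        High     1882      45.9
```

(areas in km² of the classified landscape; percentages of the study-area
extent), plus per-scenario suitability, binary and MESS rasters and a
range-change table (`pct_change = 100 * (future - present) / present`, with
the altitude distribution of high-suitability cells).

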