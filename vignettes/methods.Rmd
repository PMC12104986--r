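---
title: "Presence-only maximum-entropy range modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only maximum-entropy range modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A presence-background model treats the species' occurrence locations as
draws from an unknown distribution over the landscape's grid cells and
estimates that distribution as the Gibbs density

$$ p(x) \;=\; \frac{\exp\big(\sum_j \beta_j f_j(x)\big)}{Z},
   \qquad Z = \sum_{x \in \text{background}} \exp\Big(\sum_j \beta_j f_j(x)\Big), $$

the maximum-entropy distribution subject to (softened) constraints that the
expected feature values match their presence-sample means. The background
is a uniform sample of cell centroids describing what environments are
*available*; it contains no absence information.

`maxent()` maximizes the penalized presence log-likelihood

$$ \frac{1}{m}\sum_{i=1}^m \eta(x_i) \;-\; \log Z
   \;-\; \sum_j \lambda_j |\beta_j|, \qquad \eta = \textstyle\sum_j \beta_j f_j , $$

a convex problem solved by FISTA (accelerated proximal gradient with
backtracking line search and adaptive restart) on the exact objective,
with soft-thresholding handling the L1 term. Convergence is declared when
the relative objective change stays below `tol` (default `1e-7`) for three
iterations, with a 10,000-iteration cap; when two adaptive restarts occur
back to back the iterate can no longer improve at floating-point
resolution and is likewise accepted. Tests verify the optimum against an
independent grid-search/`optim()` path on small discrete problems.

### Features

Continuous predictors are rescaled to $[0,1]$ by their training range —
learned from the *combined* presence + background sample, since the
background characterizes the available environment. Feature classes:

| class | form | count per variable |
|---|---|---|
| L | $v$ | 1 |
| Q | $v^2$ | 1 |
| P | $v_a v_b$ (distinct pairs) | — |
| H | $\max(0, (v-t)/(1-t))$ and $\max(0, (t-v)/t)$ | 2 per knot |
| T | $\mathbf{1}[v > t]$ | 1 per knot |

Hinge/threshold knots sit at empirical quantiles, 50 per variable per
direction by default (configurable; the bundled demo uses 8 to stay
light). Categorical predictors always expand to one indicator per class
observed in training, whatever the class configuration. Constant
variables are dropped with a warning.

### Regularization

$\lambda_j = r \cdot \mathrm{base}(\text{class}_j, m) \cdot s_j / \sqrt{m}$,
where $r$ is the global multiplier (the main tuning knob: larger means
sparser and smoother), $m$ the presence count, $s_j$ the feature's
standard deviation over the presence sample (floored at $10^{-3}$ so the
problem stays bounded when a feature is constant among presences), and
`base` the published MaxEnt default tables — e.g. linear/quadratic/product
interpolate from 1.0 below 10 presences to 0.05 at 100+. These defaults
are exposed in code (`reg_base`) so any deviation is explicit.

Note a consequence worth knowing: at large $m$ the L1 threshold
($0.05\, s_j/\sqrt m$) lies *below* the sampling noise of the presence
feature means ($s_j/\sqrt m$), so a no-signal dataset still yields small
non-zero coefficients of order noise/curvature. The penalty bounds noise,
it does not null it; only in the exact no-signal limit (presences
distributed as the background itself) do all coefficients vanish.

### Outputs

Raw output is $p(x)$ normalized over the training background (it sums
to 1 there; this is audited on every fitted model). The cloglog output is
$1 - \exp(-e^{H}\,\mathrm{raw})$ with $H$ the entropy of the fitted raw
distribution; it is a monotone transform calibrated so that a cell
expected to hold one individual scores $1 - 1/e \approx 0.632$ — which is
also why a fully regularized (uniform) model predicts exactly 0.632
everywhere. When a model is transferred to scenario conditions,
predictors are clamped to the training range by default; clamping is off
for within-range prediction.

### Importance and curves

Permutation importance permutes one variable jointly across presences and
background (every feature built from it is rebuilt), measures the
training-AUC drop, averages over rounds, and normalizes the drops to sum
to 100. Percent contribution is a coefficient-magnitude proxy,
$|\beta_j| \cdot \mathrm{sd}(f_j)$ over the background summed per variable
(products split evenly between their two variables) and normalized to
100. The original MaxEnt contribution is bookkeeping internal to its
sequential optimizer and is not reproducible from a stated formula; the
proxy preserves its intent — how much of the linear predictor's variation
a variable carries — so contribution tables should be compared by ranking,
not digit by digit. Response curves sweep one variable across its
training range with the other continuous variables fixed at their
background mean (median available) and categorical ones at their mode.

## Evaluation and tuning

**Spatial blocks.** Fold structure uses the four quadrants at the median
longitude and latitude of the presences (background split the same way);
a k-means-on-coordinates alternative is available. Quadrant splits keep
per-axis presence counts balanced to within one and give spatially
contiguous validation folds, which is what limits the optimism that
random folds suffer under spatial autocorrelation. A quadrant without
presences is an error suggesting a smaller k.

**Metrics.** AUC is the rank-based (Mann-Whitney) form with ties counted
half, invariant under monotone transforms. AICc uses
$k$ = non-zero coefficients and the presence log-likelihood under the raw
output standardized over the background (consistent with fitting);
$n \le k+1$ returns $+\infty$ with a warning so such a model cannot win
selection. The Continuous Boyce Index uses 101 windows of width 10% of
the prediction range and Spearman correlation (average ranks on ties)
between the presence-to-expected ratio and the window midpoints. Because
adjacent windows overlap, a *single* null CBI is noisy (sd ≈ 0.3); tests
therefore check the null's mean over replicates rather than one draw.

**Grid search.** `tune_maxent()` crosses feature-class families
(L, LQ, LQH, LQHP, LQHPT) with multipliers 0.5–5.0 in steps of 0.5 — 50
candidates — fitting each on the full data for AICc and running block CV
for AUC difference and CBI. The table is ranked by AICc (ties: fewer
parameters, then lower multiplier). The returned selection minimizes mean
AUC difference and maximizes mean CBI, optionally inside one caller-chosen
family; judging response-curve plausibility (step-like threshold artifacts
versus smooth, interpretable shapes) is deliberately left to the analyst,
with per-candidate curves exportable for inspection.

## Thresholds, classes, scenarios, MESS

Thresholds from training-presence predictions: MTP (the minimum), P10
(10th percentile, linear interpolation between order statistics — the
convention matters at these sample sizes and is stated because different
quantile types disagree in the second decimal), and the fixed 1 − 1/e.
Classes are half-open downwards — High $(0.632, 1]$, Moderate
$(P10, 0.632]$, Low $(MTP, P10]$, Negligible $[0, MTP]$ — so a cell
exactly at a threshold joins the lower class; only the top boundary is
fixed by the "exceeding 0.632" definition, the rest is a convention made
explicit here. Class areas are cell counts times cell area and always sum
to the classified extent; percentages are taken against the full
non-nodata study extent. Scenario projection predicts with clamping,
classifies binary at the fixed threshold, and reports high-suitability
area, percent change $100(\text{future}-\text{present})/\text{present}$,
and the quantiles of a DEM over high cells (the upslope-shift summary).
MESS follows the standard per-variable similarity with strict
"fraction below" and the four branches at $f = 0$, $(0,50]$, $(50,100)$,
$f = 100$, taking the minimum over variables; negative cells flag novel
conditions where predictions are extrapolations.

## The virtual-species generator

`generate_env_stack()` mixes independent Gaussian noise fields through the
Cholesky factor of a target correlation matrix and Gaussian-smooths each
mixed field with the same kernel (length-scale in cells; smoothing
preserves the cross-correlations in expectation but shrinks the effective
sample, hence the ±0.05 empirical tolerance). The categorical layer
quantile-slices an auxiliary smooth field, giving spatially coherent
patches like real soil maps. Truths compose per-variable responses —
unimodal Gaussian bumps, linear, quadratic, or per-class weights — either
on the logistic scale (no responses ⇒ constant 0.5) or as a clipped
product. Presences are drawn with probability proportional to suitability
times an optional bias surface, one record per draw at the cell centroid
plus sub-cell jitter. Future scenarios add per-layer offsets to continuous
layers only; categorical and topographic layers are frozen.

The **benchmark species** (`make_benchmark()`) is the package's reference
truth: a 160 × 160 lattice of 1-km cells (25,600 cells, so the standard
20,000-point background fits without replacement), eight continuous
layers with two strongly correlated pairs (|r| = 0.85 and 0.75, so
collinearity screening has work to do), a five-class soil layer, unimodal
responses on two layers (centers 0.4 and −0.2 in z-score units, widths
0.8 and 1.0, heights 4 and 3), mild soil preferences, and a logistic
offset of −6 keeping mean suitability near 0.3 — a strongly structured,
moderately prevalent niche, as a sporadic tree species has. A Gaussian
bump is exactly quadratic on the link scale, so an L+Q fit can represent
this truth; with 500 presences the fitted cloglog surface tracks the true
suitability at Spearman ≈ 0.95 and the response-curve optimum lands
within ~1% of the variable's range. What passing these checks does *not*
show: robustness to sampling bias, positional error, non-equilibrium
occupancy, or predictor measurement error — real occurrence data have all
four, the generator (by design) has none unless a bias surface is
supplied.

The bundled demo (`make_demo()`) is a smaller 64 × 64 variant with 300
presences, 1,000 background points and 8 hinge knots, sized so the full
50-candidate tuning grid plus projections and MESS complete in roughly
half a minute on one CPU; the tests and the acceptance script use these
sizes.

## Numerical and design notes

- Cell membership is half-open (a point on a shared edge belongs to the
  cell on its right/below; the top and left grid edges are inside), so
  gridding is unambiguous and idempotent.
- Exact duplicate records (same coordinates and source) collapse before
  gridding; near-duplicate heuristics are out of scope.
- No reprojection is attempted: a CRS label mismatch between occurrences
  and grid is an error, matching grids are the caller's responsibility.
- The Pearson matrix for variable selection is computed on a fixed seeded
  sample of up to 10,000 non-nodata cells — bounded cost, stable
  estimates; categorical layers are exempt from Pearson/VIF screening
  (undefined for nominal codes) and always kept. Removal ties break
  toward the lexicographically later name, making the removal order
  deterministic. Two mutually violating priority variables raise an
  irreducible-conflict error rather than a silent choice.
- Protection overlays count boundary points as protected (inclusive
  containment) — the conservative choice for conservation counts.
- Rasters travel as plain-text ESRI ASCII grids with a `.prj` sidecar for
  the CRS label; models serialize to JSON.

## Limitations

Percent-contribution tables are a proxy (see above). The block
constructor assumes presences spread over all quadrants. The Gibbs
normalizer is background-relative, so raw values are comparable only
within one background set. Very large landscapes are limited by the
dense in-memory matrix per layer.
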