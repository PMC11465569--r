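---
title: "Methods: temporal-grid step-selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-grid step-selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## The model

A step-selection function (SSF) treats each observed movement step as a
choice among alternatives: the endpoint the animal actually used versus
endpoints it could have reached. With one matched random step per observed
step, the likelihood is that of 1:1 matched case-control conditional
logistic regression. For a single covariate $x$ measured at the two
endpoints of pair $i$,

$$\ell(\beta) = \sum_i \left[\beta x^{obs}_i -
  \log\!\left(e^{\beta x^{obs}_i} + e^{\beta x^{rand}_i}\right)\right]
  = \sum_i \log \sigma(\beta d_i), \qquad d_i = x^{obs}_i - x^{rand}_i,$$

where $\sigma$ is the logistic function. Only *informative* pairs
($d_i \neq 0$) contribute. $\exp(\beta)$ is the relative selection
strength (RSS): how many times more likely the habitat is to be chosen
over the alternative at equal availability.

The temporal dimension enters by *stratifying time, not the model*: the
pairs are partitioned into 26 fourteen-day periods $\times$ 24 clock
hours (624 cells), the seven single-covariate models are fitted
independently in every cell (4,368 fits), and the resulting coefficient
fields $\beta(\text{period}, \text{hour})$ are treated as data for a
second-stage Gaussian additive model per covariate:

$$\beta = \alpha + f_{hour}(h) + f_{year}(p) + f_{h \times p}(h, p) + \varepsilon,$$

with cyclic penalized splines for both margins and their tensor-product
interaction. Predictions on the 365-day $\times$ 24-hour grid are the
package's *selection surfaces*, from which all summary metrics derive.

Fitting each temporal cell independently and smoothing afterwards keeps
the first stage exactly the conditional MLE (no pooling bias, trivially
parallel, robust to single-cell failures) at the cost of ignoring the
per-cell standard errors in the second stage; the smoothing model is
deliberately the plain unweighted Gaussian fit on the coefficients.

## Key parameters

* **Outlier rule** (`max_step_km = 15`, `max_interval_h = 1`): fixes
  implying speeds above 15 km/h are treated as positional errors. The
  rule is applied *iteratively* — the later fix of an offending pair is
  removed and the new neighbour pair re-checked — so one spike never
  drags plausible neighbours out. Applying the threshold to the implied
  speed (scaled to the actual gap) rather than the raw displacement makes
  the rule well-defined for any gap.
* **Regularization** (`target_min = 60`, `tol_min = 15`, `min_burst = 3`):
  a greedy forward scan keeps fixes whose gap from the last kept fix lies
  in [45, 75] min; any other gap closes the burst and anchors a new one.
  Three fixes are the minimum that defines one turning angle.
* **Temporal grid** (14-day periods, 1-hour intervals): 26 seasonal
  blocks keep the seasonal and diel resolutions comparable (26 vs 24
  levels). $26 \times 14 = 364$, so days 365–366 are absorbed into period
  26 rather than opening a 27th, one-day block.
* **Cell assignment**: a pair belongs to the cell of the *observed
  step's end timestamp* — the moment and place where its covariates are
  measured.
* **Subsampling** (`target_pairs = 863`): cells are equalized to 863
  pairs (1,726 locations) so every cell's coefficient has comparable
  sampling noise; whole pairs are sampled, never single locations,
  because the conditional likelihood needs intact strata.
* **Basis dimensions** (`k_hour = 5`, `k_year = 10`): deliberately small
  bases cap the wiggliness of the diel and seasonal effects; the penalty
  then shrinks within that cap.
* **Distance standardization**: raw distances to roads and settlements
  are z-scored (sample SD) over *all* endpoints pooled across the whole
  dataset, not per cell, so the distance-model coefficients live on one
  common scale across the 624 cells — a prerequisite for smoothing them.

## The synthetic-data generator

`make_landscape()` builds a patchy nine-class mosaic by nearest-seed
(Voronoi) tessellation of random patch seeds, stamps straight-line roads
and clustered settlements, and computes exact Euclidean distance grids.
Only class membership and the two distance fields matter downstream, so
this deliberately simple construction suffices and keeps availability
controllable through the seed counts.

`simulate_tracks()` is a forward model of the assumed selection process:
at each hourly fix, $M = 10$ candidate endpoints are drawn (gamma step
lengths, von Mises turns relative to the previous bearing; the first move
uses uniform bearings) and one is chosen with probability
$\propto \exp(\sum_h \beta_h(d, t)\, x_h)$, where each
$\beta_h(d, t)$ is a harmonic surface
$a_0 + a_{hour}\cos(2\pi t/24 - \phi_{hour}) +
a_{year}\cos(2\pi d/365 - \phi_{year}) +
a_{int}\cos(2\pi t/24)\cos(2\pi d/365)$ — periodic in both arguments,
hence exactly the kind of signal the cyclic smoothers can represent.
Candidates leaving the landscape are redrawn (up to 100 rounds, then
reflected), which keeps the kernel unbiased in the interior where
recovery is assessed. One global movement kernel serves all individuals,
matching a pooled-per-cell analysis.

Defaults describe the targeted study design: hourly fixes over one full
(non-leap) calendar year, several individuals, mean step 300 m
(gamma shape 2, scale 150 m — a realistic hourly displacement for a large
browser), mild heading persistence ($\kappa = 0.5$).

What the generator does *not* emulate: home ranges or migration, serial
autocorrelation beyond first-order heading persistence, fix loss and
irregular sampling, habitat-dependent movement kernels, and inter-annual
change. Passing recovery tests therefore demonstrates the *estimator* is
correct for the assumed choice process, not that real tracks satisfy
those assumptions.

The default recovery experiment uses a 150 × 150 grid of 20 m cells
(3 km × 3 km): a larger extent than the 10 m default keeps boundary
contact rare for 300 m steps while the mosaic grain stays well resolved.

## Numerical choices

* **Newton–Raphson on pair differences** with step-halving (the
  likelihood is concave; halving only guards extreme starts), converged
  at $|\text{score}| < 10^{-8}$, SE from observed information.
  *Degenerate configurations are flagged, not estimated*: no informative
  pairs → non-estimable; all informative differences of one sign
  (complete separation, infinite MLE) → $\beta$ reported at $\pm 10$ and
  excluded from smoothing.
* **Cyclic P-splines**: uniform cubic B-splines on $k$ knots folded at
  the period boundary (rows for $x$ and $x + P$ identical), circulant
  second-difference penalty whose null space is the constant. Marginal
  smooths are centered via a sum-to-zero reparameterization over the
  training design; the tensor interaction is built from the constrained
  marginals with penalty $S_h \otimes I + I \otimes S_y$.
* **Smoothing-parameter selection**: GCV minimized over a fixed
  log-spaced grid ($10^{-3} \ldots 10^{7}$), one value per term —
  deterministic, no stochastic optimizer. The grid is walked from
  heaviest to lightest smoothing and improvements below a numerical
  tolerance do not displace the incumbent, so exact ties (e.g. a
  constant response, which every candidate fits perfectly) resolve to
  the smoothest fit. A boundary minimum triggers a warning.
* **Year coordinate**: the second stage uses the 26-period cycle that
  the grid defines; day-resolution predictions map $d \mapsto (d-1)/14$,
  clipped into period 26 for days 365–366.
* **Raster lookup**: half-open cells on both axes (a point on a shared
  edge belongs to the cell with the larger index), stated so covariate
  extraction is bit-reproducible.
* **Permutation significance**: the response is permuted across cells
  and refitted *at the smoothing parameters selected for the observed
  response*; each term's explained sum of squares is compared to its
  permutation null, $p = (1 + \#\{perm \ge obs\})/(n_{perm} + 1)$.
  Re-running GCV per permutation would multiply the cost several
  hundredfold for no change in exchangeability under the null; the
  package verifies the resulting type-I error empirically (within three
  binomial SEs of 0.05 over 200 noise datasets).
* **Seeds**: one master seed per run; per-stage and per-cell seeds are
  derived by hashing the stage/cell key, so cell results do not depend
  on iteration order and the whole run is bit-reproducible.

## Design decisions on genuinely open points

* **Preference tie rule**: $\beta > 0$ is preference, $\beta \le 0$
  avoidance (exact zeros count as avoidance).
* **Repeatability**: Pearson correlations of the 7-model coefficient
  vectors predicted at each cell's midpoint day and hour, over all
  unordered cell pairs; Spearman is available as an option.
* **Fold differences**: on a positive surface, the diel fold is
  max/min of the hourly means (averaged across days) and the seasonal
  fold max/min of the daily means — the simplest marginal-ratio
  definition; it is scale-invariant. For signed per-habitat surfaces the
  recovery experiment applies it to $\exp(\beta)$.
* **Interfaces**: the analysis is driven from R (`ssf_config()` +
  `run_ssf_pipeline()`, or the lower-level functions); landscape
  interchange uses a dependency-free plain-text ASCII grid format.

## Validation problem sizes

The test-suite and acceptance-script experiments use: a full-coverage
synthetic pairs table at 900 pairs/cell (subsampled to 863) for the
structural counts; 1,000 binary and 200 continuous datasets for the
solver-oracle agreement (tolerances $10^{-6}$ and $10^{-4}$); $n =
20{,}000$ draws for kernel recovery (within 5% of truth); 20 simulated
individual-years for end-to-end recovery (surface correlation $\ge 0.7$,
observed $\approx 0.98$); and 200 noise datasets × 99 permutations for
the type-I calibration.

## Known limitations

* Single-covariate models by design: no joint multi-covariate SSF, no
  random effects across individuals, no sandwich SEs.
* The second stage ignores first-stage SEs (unweighted Gaussian fit);
  cells with more informative pairs are not up-weighted.
* The smoothing machinery is a deliberately transparent cyclic P-spline
  with grid-GCV; its effective degrees of freedom and significance
  measures are analogues of, not replicas of, mainstream GAM software.
* Coordinates must be projected meters and timestamps UTC; no CRS
  transforms or local-time handling.
* The 365-day year treats day 366 as day 365; sub-hourly designs are
  supported by the grid code but untested against the reference
  configuration.
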