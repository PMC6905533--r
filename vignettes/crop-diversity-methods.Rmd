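---
title: "Methods: crop diversity, turnover and intensification from district panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crop diversity, turnover and intensification from district panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropdiv)
```

This vignette documents the models implemented in `cropdiv`, the
assumptions behind them, the numerical choices that matter, and what the
synthetic-data generator does and does not emulate.

## 1. The panel and its harmonization

The unit of data is a record (region, year, crop, area in hectares,
production in tonnes). All analysis assumes (region, year, crop) keys are
unique, values are non-negative, and every district resolves to a state.
Three pre-processing steps precede any statistic:

* **Combining overlapping sources.** Where two compilations report the
  same key, `combine_sources()` takes their arithmetic mean; keys in one
  source pass through. Combination is applied after region harmonization
  in the pipeline — the order is not forced by the data model, but
  harmonizing first means the averaged series always refers to one stable
  boundary definition.
* **Boundary harmonization.** Administrative districts split over time.
  `harmonize_regions()` maps every observed district through an
  idempotent merge map onto base-year (default 1966) districts and sums
  areas and productions. Total area per (year, crop) is conserved
  exactly; the tests verify this to 1e-6 relative tolerance on random
  panels. The number of districts is a property of the input, never a
  package constant.
* **Gap imputation.** A (region, crop) series qualifies when it has at
  least `min_values = 10` non-missing observations over its whole span
  (the rule is deliberately window-free). Interior gaps are filled by
  linear interpolation between the nearest flanking observations —
  100 ha in 1980 and 200 ha in 1982 give 150 ha for a missing 1981 —
  and leading/trailing gaps are never extrapolated, since interpolation
  "between the available values" has no support outside them. Imputed
  records carry a flag. Production is imputable by the same rule but off
  by default; the rule is defined for area, and yields computed from
  mixed imputed/observed numerators and denominators are hard to reason
  about.

Yields are always computed aggregate-first: total production over total
area at the reporting level, in kg/ha. Averaging district yields would
weight small and large districts equally and is never done.

## 2. Effective number of species and the crop-count adjustment

Diversity is `D = exp(H)` with `H` the Shannon entropy of crop-area
proportions over crops with strictly positive area. `D` is the effective
number of species: `n` equally abundant crops give exactly `D = n`, any
unevenness gives less. Crops with zero reported area are excluded from
both the proportions and the crop count; a mix with no positive area is
an error, not a zero.

### Why adjust for crop count

District compilations report 20–24 major crops; country-level series
report 80+. Since `D` can only grow as more crops are distinguished,
raw values are not comparable across reporting lists. The adjustment
estimates what `D` would have been had `x* = 83` crops been reported: fit

\[ D(x) = a + b\,e^{-c\,x} \]

to the diversity-versus-crop-count curve of the observed mix and evaluate
at `x*`. By convention all sub-national diversity is reported adjusted
(`run_config(adjust = TRUE)`, the default) and the country-level series —
already on the full crop list — is reported raw.

### How the curve is built, and a pitfall

`subsample_diversity_curve()` supports two subset rules:

* **`method = "random"`** draws, for every size `x`, uniform random
  subsets of `x` crops, renormalizes their proportions and averages `D`
  over `reps = 200` replicates (every integer size in `[2, n]` by
  default; the replicate mean is what the fit sees, though per-replicate
  output is available). This is the natural reading of "subsampling",
  and the package implements it faithfully — with a warning to users:
  a uniform random subset inherits the evenness of the full mix, so its
  expected diversity is close to **proportional** to `x` for almost any
  composition. A near-linear curve contains almost no information about
  saturation, and the three-parameter exponential fit responds by
  driving `c` toward zero with an arbitrarily large asymptote. The fit
  diagnostics catch this (below), but the adjustment is then undefined.
* **`method = "rank"`** (the default for `adjusted_diversity()`) takes,
  for each `x`, the `x` **largest** crops, renormalizes and computes `D`.
  This models how reporting lists actually shrink — a 20-crop dataset
  contains the 20 most widespread crops, not a random twenty — and
  produces a deterministic, monotone curve that saturates at the raw
  diversity. Under this rule the canonical behaviours hold: a
  dominance-heavy mix saturates almost immediately (adjustment barely
  exceeds raw), and the perfectly even mix gives the pathological exact
  line `D(x) = x`, which is flagged rather than extrapolated.

The tests exercise both rules; the Monte-Carlo mean of the random rule is
checked against exhaustive enumeration over all subsets at small `n`.

### Fitting and degeneracy

The curve is fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm`), with `c` bounded below by 1e-6 and heuristic starts
(`a0` = largest observed `D`, `b0` = `D` at the smallest `x` minus `a0`,
`c0 = 0.1`) plus up to 5 jittered restarts. A converged fit is flagged
**degenerate** when any of these hold:

* `c` sits at its lower bound, or `c · range(x) < 0.2` — the curve does
  not saturate within (a few times) the observed range, so evaluating it
  at a larger `x` is pure extrapolation;
* the asymptote is implausible (`a < 0` or `a > 3·max(D)`).

A degenerate or failed fit leaves the adjusted value missing and callers
fall back to the raw value. Mixes with fewer than 5 positive crops are
never fitted (a 3-parameter curve through 3 points is meaningless).

### Partitioning and trends

For each year, `γ` is the diversity of the pooled (summed) district
areas, `α` the **unweighted** mean of district diversity values — the
plain reading of "mean district-level diversity"; an area-weighted
option exists but is off by default — and `β = γ/α` measures how
dissimilar districts are: 1 when all districts share one composition,
up to the number of districts for disjoint monocultures. Whatever
diversity variant (raw or adjusted) populates the district table is the
one entering `α`, matching the adjusted-everywhere-but-country
convention by default. Per-region change is summarized by the OLS slope
of `D` on calendar year with a two-sided t-test; regions with
`p ≥ 0.05` are classified `NS`. Constant series are classified `NS`
with slope 0 rather than erroring.

## 3. Transition matrices

Between two period means (defaults 1956–1960 and 2004–2008, means over
non-missing years only), each district's flows are built under the
conservative assumption that retained area did not move:

* diagonal for crop *i*: `min(area_t0, area_tend)`;
* total transferred area: `min(ΣL, ΣG)` where `L` and `G` are per-crop
  losses and gains; the flow from declining *i* to expanding *j* is
  proportional to `L_i · G_j`. Proportional-to-gain allocation is the
  maximum-entropy choice — the data say nothing about which expanding
  crop took over a declining crop's fields — and is isolated behind an
  `allocation` argument (`"uniform"` is provided) because it is the
  single biggest interpretive decision in this module;
* net expansion is sourced from a `__new__` row, net contraction sinks
  to an `__exit__` column, so row sums recover initial areas and column
  sums final areas exactly.

The national matrix is the **sum of district matrices**, not the matrix
of national aggregates: the within-district assumption only makes sense
district by district, and summing preserves it. The proportional variant
divides by total initial-period area. Districts or crops present in only
one period are zero-filled via `align_period_means()` before building.

## 4. Relative intensity and the model ladder

For a crop set (defaults: `{wheat}` and `{rice, wheat, sorghum,
millet}`), a district's weighted yield in a window is total crop-set
production over total crop-set area of the window period means —
aggregate-first again. `y_max` is the maximum of this quantity over all
districts and **both** analysis windows jointly ("across all
districts/years"); per-window normalization is available as an option.
`RI = yield / y_max`, so exactly one district/window attains 1 (up to
ties) and `RI` is invariant to common rescaling of areas and
productions. Districts need at least 3 of the 5 window years to be
retained; exclusions are logged, never hard-coded, since completeness
rules legitimately change the regression degrees of freedom.

The delta table holds, per district, `RI` at both windows, the initial
and final crop-set **share of district crop area** (the district
proportion, not the national one), mean diversity over each window, and
their exact differences. The ladder of candidate OLS models for `ΔD` is
`{ΔRI}`, `{ΔRI, Area₀}`, `{ΔRI, Area₀, ΔRI×Area₀}` (and the analogous
ladder when the change in crop-set area share is the response or
covariate). Selection is minimum AIC among non-rank-deficient fits; the
full comparison table (coefficients, R², AIC, residual df, n) is always
returned so selection can be audited. The significance threshold is 0.05
throughout and no multiple-testing correction is applied, matching the
plain-OLS framing; the package deliberately makes no causal claims.

The sorghum/millet baseline is a single-predictor OLS of `ΔD` on the
initial sorghum+millet area share, for regions where cereal
intensification does not describe the dynamics; a constant share across
districts is reported as rank-deficient rather than fitted.

## 5. The synthetic-data generator

`scenario_config()` defaults describe a panel structured like the
historical Indian district compilations but sized for minutes-scale test
runs: 60 base districts in 10 states, 24 crops in five roles, years
1956–2008, half the districts in each regime, 2% of interior cells
blanked, and one district split in 1980 with shares (0.4, 0.6).

* **Initial mixes** are Dirichlet draws around regime-specific role
  weights. The weights are small (sparse draws): each district
  concentrates on its own handful of crops, which is what keeps β
  around 2 rather than 1 — with identical mean mixes and large
  concentration, districts would be near-copies and β would collapse.
  Regime-A districts start with sizable wheat/rice area; regime-B
  districts are dominated by sorghum/millet.
* **Regime A (intensification)** drifts log shares toward the
  intensifying cereals at `specialization_strength = 0.03` per year,
  scaled by a district-specific yield-gain multiplier drawn uniformly
  in (0.3, 1.7). The same multiplier scales the cereal yield trend
  (0.040 t/ha/yr in regime A), so districts that intensify fastest also
  specialize fastest — the mechanism that links ΔRI to ΔD.
* **Regime B (diversification)** interpolates log shares from the
  initial mix toward a district-specific sparse Dirichlet target
  concentrated on oilseed/horticulture crops, at
  `diversification_strength = 0.025` of the way per year (capped at 1).
  Interpolation toward a target, rather than multiplicative drift, lets
  crops that start from near-zero area be adopted at all; sparsity of
  the target keeps each district's own diversity gain moderate while the
  national pool spreads over many crops — raising γ, and hence β, over
  time.
* **Yields** are linear per crop and district (role baseline + trend ×
  gain, floored at 0.05 t/ha) with multiplicative lognormal noise
  (sd 0.05) on production; log shares get yearly Gaussian noise
  (sd 0.02). District totals grow deterministically at 0.5%/yr, so the
  national area path is exact in the zero-noise limit. With all
  strengths and noises zero, shares are constant and yields exactly
  linear — the null scenario used in tests.

`inject_missing()` blanks interior cells only (never a series' first or
last year), keeping the blanked truth for recovery scoring;
`apply_split_events()` replaces a parent district by children with
partitioned areas and returns the hierarchy that merges them back, so
split-then-harmonize is an exact round trip.

**What the generator does not emulate:** spatial adjacency (neighbouring
districts are independent draws), price- or policy-driven behaviour,
reporting-list changes over time (the crop list is fixed at 24),
measurement error in area (noise enters shares and production only), and
heavy-tailed or systematically missing data (missingness is uniform over
interior cells). Tests passing on this generator therefore demonstrate
that the statistics measure what they claim on data with the assumed
structure — not that the historical compilations satisfy those
assumptions.

## 6. Reproducibility and problem sizes

All randomness in a pipeline run flows from the single `run_config()`
seed: the generator consumes it directly, and per-group subsampling
seeds are derived from it by offset, so reruns are byte-identical (the
suite checks output checksums). The test suite works at deliberately
small scale — panels of 4–60 districts, recovery experiments at n = 200
with 50–100 replicate seeds, 20 seeds for the end-to-end signature —
chosen so the full suite completes in a few minutes while keeping every
assertion's power high enough to be meaningful. Summary percentiles use
R's default type-7 quantile (linear interpolation between order
statistics).

## 7. Known limitations

* The crop-count adjustment extrapolates a parametric curve; for mixes
  whose accumulation curve has not begun to flatten by the observed crop
  count, the flag-and-fall-back behaviour means adjusted and raw values
  mix in downstream summaries (the `fit_ok` column records which is
  which).
* The transition matrix is an accounting identity under an allocation
  rule, not an estimate of gross land-use flows; only its margins are
  data.
* OLS on district deltas ignores spatial autocorrelation; standard
  errors are likely optimistic on real data.
* `RI` compares districts to the single best district-period; it is
  sensitive to outliers in the yield maximum by construction. Ties at
  the maximum are all reported as RI = 1.
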