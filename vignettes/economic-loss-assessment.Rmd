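---
title: "Methods: spatially explicit economic-loss assessment for invasive species"
author: "invadeloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially explicit economic-loss assessment for invasive species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`invadeloss` estimates the sectoral economic losses caused by an invading
pest from three heterogeneous inputs: administrative presence–absence
bulletins, presence-only occurrence points, and district-by-year sectoral
output tables. The pipeline has three conceptual blocks — spatial matching
of all layers onto one grid, causal loss estimation on a unit-year panel,
and potential-loss projection over habitat suitability — plus a synthetic
scenario generator that provides ground truth for testing. This vignette
records the models, the assumptions behind them, the parameter defaults,
and the design decisions that were genuinely open.

## The shared grid

Every layer lives on one planar `grid_spec`: top-left origin, square cells
(default 1000 m, i.e. 1 km² = 100 ha per cell), 0-based row-major
convention with cell centers at `origin + (index − 0.5)·cell_size` and
half-open point-to-cell intervals. A planar CRS is assumed throughout; no
geodesic computation is performed, which is appropriate for projected
regional grids at this scale. Rasters are persisted as ESRI ASCII grids, a
plain-text format that carries the full grid specification and is readable
by any GIS; nodata sentinels are −9999 for continuous layers and 255 for
categorical ones, mapped to `NA` in memory so masked cells are excluded
from every statistic.

## Severity coefficient

Two evidence sources are fused into a per-cell infestation severity in
[0, 1]:

* **Presence–absence reclassification.** Cells of an infested unit receive
  the host weight of their land-use class (defaults: broadleaf forest 1.0,
  arable 0.8, other forest 0.6, grassland 0.2, everything else 0). This
  encodes the host preference of a defoliating forest/crop pest instead of
  spreading presence uniformly over the unit.
* **IDW occurrence surface.** Raw influence at a cell center is
  `Σ_p 1/d^p` with `p = 2` by default. The description of occurrence decay
  as "exponential" in parts of the literature conflicts with the printed
  power-law kernel; we implement the formula (a power law), with the
  exponent configurable. A cell containing a point would have infinite
  influence; it is assigned the largest finite influence on the raster
  before min–max normalization, preserving "maximum at the source" without
  dividing by zero.

The severity raster is `clip(w_pa·PA + w_po·PO, 0, 1)`. The relative
weighting of the two layers is not a settled quantity in the field; we
default to (0.5, 0.5) and expose both weights. Normalization of the IDW
surface is per-year (each year's severity uses only that year's records,
with no temporal carry-over), and severe-infestation counting uses a strict
`severity > 0.75` threshold.

## Dasymetric disaggregation

District sectoral output is distributed over the district's cells with
allocation weights derived from provincial aggregates: the weight of
(sector, class) is the provincial output intensity of the sector on its
linked class — cultivation→arable, forestry→both forest classes,
husbandry→grassland, fishery→water. Cross-sector leakage is disallowed:
each sector draws only from its linked classes, and urban/bare cells are
masked with weight exactly 0. Weights are time-invariant. Units with zero
allocation mass for a sector cannot absorb that sector's output; their
cells become nodata and the run warns, rather than silently inventing
mass. Conservation (aggregate of cells = table value) holds to numerical
precision wherever mass is positive and is enforced by test. Currency is
stored in ten-thousand-CNY units to match the convention of provincial
statistical series.

## GeoDetector

The factor detector is `q = 1 − (Σ_h n_h σ²_h)/(n σ²)`. We use
*population* (divide-by-n) variances throughout: with sample variances,
strata of size one are undefined and tiny strata can push q outside
[0, 1], whereas population variances keep the law of total variance exact
and q in [0, 1] always (property-tested over random stratifications, and
against a brute-force grouped-variance oracle to 1e−12). Strata with a
single cell contribute zero within-stratum variance and are kept; a
minimum-stratum-size filter exists but is off by default. Discretization
offers quantile (default, 5 classes), equal-interval and natural-breaks
methods; natural breaks is implemented as deterministic 1-D k-means with
quantile-seeded centers, a standard approximation to Jenks optimization
(no Jenks implementation is available among our dependencies, and the
k-means objective is the same within-class sum of squares).

The interaction detector computes q on the cross-classification of two
factors and classifies the pair with the five standard inequalities. The
only boundary case, `q12 = q1 + q2` (independence), is checked first with
tolerance `τ = 1e−9`; all other comparisons are strict. Published
applications occasionally label an interaction inconsistently with these
inequalities; the implementation always follows the inequalities.
Significance testing of q is out of scope.

## Staggered DID

The loss model is the two-way fixed-effects regression
`Y_it = α + β D_it + θ'W_it + μ_i + γ_t + ε_it` with absorbing treatment
(`D_it = 1` from a unit's first infestation year onward). Two treatment
codings are supported:

* `"D"` — the binary indicator, in which case β is a per-unit effect;
* `"X"` (default when available) — the intensity `X_it = cells_i · D_it`,
  where `cells_i` counts the unit's cells in the sector's linked land-use
  classes. β is then a *per-cell* annual effect, which is the natural scale
  for combining with raster suitability downstream and mirrors the
  treatment-intensity tradition in staggered adoption designs.

Estimation is OLS with unit and year dummies — algebraically identical to
the two-way within transformation, which the test suite verifies against an
independent demeaning estimator to 1e−8. Standard errors are
cluster-robust by unit by default (p-values on G − 1 degrees of freedom);
heteroskedasticity-only HC1 is available. Counterfactual output is
`Y − βD` with all other terms at observed values, and annual losses are
the deflator-adjusted counterfactual-minus-observed sums.

Panels that cannot identify β are rejected rather than fit: fewer than two
units or years, no treated or no untreated observations, or treatment
constant within every unit (collinear with the unit effects). Plain TWFE
is used deliberately, despite its known caveats under heterogeneous
treatment effects in staggered designs; no Callaway–Sant'Anna-style
correction is applied, and with the homogeneous per-cell effects of the
synthetic generator TWFE is unbiased (verified by the recovery study
below). Because mixed resolutions are common in source data (per-cell
coefficients quoted on a 30 m reference cell, analysis on 1-km grids), the
projection stage exposes an explicit `area_scaling` constant —
`(1000/30)² ≈ 1111` cells per km² for that case — instead of converting
silently; the default 1 keeps β on the analysis cell.

## Potential-loss projection

Suitability rasters in [0, 1] from any external SDM are classified at
thresholds (0.25, 0.5, 0.75) — class cut-offs are rarely published, so the
quartile convention is the default and the thresholds are echoed in the
output metadata. Projected loss per sector is `|β| · area_scaling · A`
with `A` the count of medium-high/high cells in the sector's linked
classes; the 95% interval maps `β ∓ 1.96·SE` through the same linear
function (delta method), making the interval width exactly
`2·1.96·SE·A·area_scaling` — a property the tests check, along with exact
linearity in `A` and `|β|` and monotonicity in the suitability surface.
Sectors with `p ≥ 0.05` are excluded by default, consistent with not
monetizing effects indistinguishable from zero. The total row is exactly
additive over the reported sectors; published totals sometimes are not,
and the exactly-additive convention surfaces such inconsistencies instead
of hiding them.

## Synthetic scenario generator

The generator emulates the structure of a regional invasion and economy so
that every stage has known ground truth:

* **Landscape** — contiguous administrative units by nearest-seed
  tessellation; land-use classes carved from a smoothed Gaussian field at
  exact quantile shares (defaults: arable 45%, forest 32% split 20/12
  between broadleaf and other, grassland 10%, water 6%, urban 5%, bare 2% —
  an agroforestry-mosaic profile); a driver stack in [0, 1] including a
  corridor-like road-density field through the invasion origin and a
  smooth population-density field.
* **Spread** — a deterministic wavefront on the 8-neighbor cell graph with
  local speed `spread_rate · (1 + corridor_strength · road)`, the simplest
  process that reproduces a clustered-then-contiguous two-phase pattern
  with faster movement along transport corridors. Severity after arrival
  is a saturating ramp scaled by a host multiplier; a unit's first
  infestation year is the first year any of its cells exceeds severity
  0.5. Occurrence points are Poisson-sampled with intensity proportional
  to severity. Defaults: spread_rate 4 cells/year, corridor_strength 1.5,
  chosen so that a 100×100 scenario over 12 years retains never-treated
  control units while the corridor effect is visible.
* **Panel** — `Y = α + μ_i + γ_t + θ·W + β_s·cells_{i,s}·D_it + ε`, with
  planted α, unit effects μ ~ N(0, 10), a mild year trend in γ, one
  time-varying control (θ = 0.5) and ε ~ N(0, 0.5). The planted per-cell
  sectoral effects default to forestry −0.163, cultivation −0.021,
  husbandry +0.005, fishery −0.034 — magnitudes characteristic of a
  defoliating forest pest whose damage concentrates in forestry, barely
  touches cultivation, and leaves husbandry/fishery near zero. Ground
  truth (α, β, θ, μ, γ) is emitted in machine-readable form.
* **Suitability** — a smoothed host-density field modulated by rainfall,
  zero wherever hosts are absent; it emulates an SDM output, no niche
  model is fitted.

Each generator draws from its own RNG stream derived from the master seed,
so stages are reproducible independently; fixed seed implies bit-identical
outputs, and the pipeline's CSV outputs are byte-identical across reruns
(tested).

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: observation bias in occurrence points (ours
are unbiased severity samples; real presence-only data oversample roads
and towns), reporting lags and misclassification in administrative
bulletins, anticipation effects and policy responses that violate the
parallel-trends assumption, heterogeneous treatment effects across units
and cohorts, and spatially autocorrelated economic noise. Recovery results
on synthetic panels therefore demonstrate estimator correctness, not
robustness to those failure modes.

## Numerical choices and degenerate inputs

* Population variances in q (range exactness); equality tolerance 1e−9
  only on the independence branch.
* IDW source-cell cap (largest finite influence) before min–max
  normalization; min–max maps a constant surface to 0.
* Resampling: `nearest` is mandatory for categorical rasters; `sum`
  conserves the global total (tested to 1e−9 relative).
* Constant rasters are rejected by discretization and by Moran's I
  (undefined statistics), degenerate panels by the DID fitter; empty point
  sets are input errors.
* Moran's I uses queen contiguity, row-standardized, by default — the
  common raster convention — with truncated edge neighborhoods and no
  wraparound; a simple permutation p-value is available.

## Problem sizes

The test suite exercises 20×20–50×50 grids against brute-force oracles,
1000 random stratifications for the q-range property, a 100-replicate
recovery study (200 units × 12 years, noise s.d. 0.5) for DID bias and
95%-interval coverage, and two full 100×100, 50-unit, 12-year pipeline
runs for byte-level reproducibility. These sizes give stable Monte Carlo
checks while keeping the default suite fast on a single CPU.

## Known limitations

* TWFE under genuinely heterogeneous, dynamics-laden treatment effects can
  be biased; event-study diagnostics and modern staggered-DID estimators
  are out of scope.
* The cluster-robust 95% intervals are asymptotic in the number of units;
  with very few units a wild bootstrap would be preferable.
* Allocation weights are time-invariant and strictly sector-linked;
  economies with strong cross-sector land use (agroforestry proper) are
  only approximated.
* Suitability classification thresholds are conventions; conclusions
  should be checked for sensitivity to them.
* No reprojection: all inputs must already share one planar CRS and
  resolution, up to the provided resampling.
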