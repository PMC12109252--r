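# invadeloss

Spatially explicit economic-loss assessment for invasive alien species.

Regional records of a biological invasion rarely arrive on one spatial
support: agencies publish coarse presence–absence bulletins by
administrative unit, citizen-science portals contribute presence-only
occurrence points, and the economic outcomes of interest are district-level
sectoral gross output tables. `invadeloss` is an R toolkit for analysts who
need to turn that mix into a defensible monetary loss estimate. It unifies
every layer onto a single planar 1-km grid, estimates causal sectoral losses
with a staggered difference-in-differences panel design, screens spatial
drivers with the GeoDetector q-statistic, and projects potential losses over
habitat-suitability surfaces produced by any external species distribution
model. A synthetic-scenario generator with known ground truth makes the
whole chain testable without access to administrative data.

## What the package computes

**Severity coefficient.** Unit-level presence–absence records are
reclassified through host-preference weights by land-use class, and
occurrence points are interpolated by inverse-distance weighting
(influence `1/d^p`, default `p = 2`). The two layers are combined cell-wise,

```
severity = clip(w_pa * PA + w_po * PO, 0, 1),
```

giving a per-cell infestation intensity in [0, 1].

**Dasymetric disaggregation.** District output `Y` for sector `s` is spread
over the district's cells proportionally to allocation weights
`w(s, class)` — provincial output intensities on each sector's linked
land-use class (cultivation→arable, forestry→forest, husbandry→grassland,
fishery→water); urban and bare land are masked with weight exactly 0.
Aggregating the cells back reproduces the input table to numerical
precision.

**Driver screening (GeoDetector).** For a stratification of the study area
into `L` strata, the factor detector is

```
q = 1 - ( Σ_h n_h σ²_h ) / ( n σ² ),   q ∈ [0, 1],
```

with population variances; `q = 1` means the factor fully controls the
spatial variation of the outcome, `q = 0` means no explanatory power. The
interaction detector classifies each factor pair into the five standard
categories (nonlinear weakening … nonlinear enhancement) by comparing
`q(X1∩X2)` with `q(X1)`, `q(X2)` and their sum.

**Loss estimation (staggered DID).** Unit-by-year panels are fit with the
two-way fixed-effects model

```
Y_it = α + β D_it + θ' W_it + μ_i + γ_t + ε_it,
```

where `D_it` switches on permanently at a unit's first infestation year
(optionally scaled by the unit's exposed cell count so `β` is a per-cell
annual effect), with cluster-robust standard errors by unit. Counterfactual
output is `Y - β D`; annual losses are the deflator-adjusted gap between
counterfactual and observed series.

**Potential-loss projection.** An external suitability raster in [0, 1] is
classified at thresholds (0.25, 0.5, 0.75); projected sectoral loss is
`|β| × eligible area` over medium-high/high cells of the sector's linked
land-use classes, with delta-method 95% intervals.

## Worked example

A full synthetic run — landscape, corridor-driven spread, panel generation,
severity matching, disaggregation, driver screening, DID estimation and
projection — from one seed:

```r
library(invadeloss)
cfg <- default_pipeline_config(seed = 1)
cfg$grid    <- list(n_rows = 60L, n_cols = 60L, cell_size = 1000)
cfg$n_units <- 25L
res <- run_pipeline(cfg, out_dir = "runs/demo")

res$did$table
#>        sector estimate std_error t_value  p_value
#> 1 cultivation -0.02034   0.00137  -14.87 1.31e-13
#> 2    forestry -0.16584   0.00173  -95.92 1.55e-32
#> 3   husbandry  0.00662   0.00483    1.37 1.83e-01
#> 4     fishery -0.02194   0.00709   -3.10 4.95e-03
```

The estimated per-cell annual effects recover the scenario's planted values
(forestry −0.163, cultivation −0.021, husbandry +0.005, fishery −0.034
output units per infested cell and year): forestry is the hardest-hit
sector, and the small positive husbandry coefficient is correctly
indistinguishable from zero (p = 0.18). Projection over the scenario's
suitability surface then yields

```r
as.data.frame(res$project)
#>   scenario      sector eligible_cells   point lower95 upper95
#> 1 baseline cultivation           1605  32.654  28.350  36.957
#> 2 baseline    forestry            994 164.846 161.478 168.215
#> 3 baseline     fishery             90   1.974   0.724   3.225
#> 4 baseline       total           2689 199.474 190.552 208.396
```

i.e. a projected total potential loss of 199.5 output units per year
(95% CI 190.6–208.4) were the pest to occupy all medium-high/high
suitability habitat, dominated by forestry. Non-significant sectors
(husbandry here) are excluded from the projection by default. Annual loss
accounting from the counterfactual series shows losses plateauing once
spread stabilizes (forestry: 191 units/year over 2020–2022 in this run),
and the final-year severity surface remains spatially clustered
(global Moran's I = 0.60).

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/scripts/invadeloss.R`.

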