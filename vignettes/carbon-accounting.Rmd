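---
title: "Land-cover change, carbon stocks and their value: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-cover change, carbon stocks and their value: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luccarbon)
```

This vignette is the package's account of the science it implements:
the models, their assumptions, the parameters that matter, the
numerical choices made where the design was genuinely open, and what
the test evidence does and does not show.

## The problem

Land-use/land-cover (LULC) change is a first-order control on regional
terrestrial carbon stocks: converting forest to settlement or grassland
to bare land releases carbon, while afforestation and abandonment
sequester it. The standard desk assessment couples three pieces:
a categorical map series (here, CORINE-derived maps reclassified to
seven IPCC-style classes), a Markov model of class transitions used to
project the next map, and a per-class carbon-density table that turns
any map (observed or projected) into a stock, a change, a CO₂
equivalence, and a monetary value. The bundled reference tables
reproduce a Calabria (Italy) case study spanning 2000–2024 at six-year
steps.

## Raster model

A `categorical_raster` is an integer class grid with a nodata code, a
square cell size in metres, an upper-left origin, and an opaque CRS
tag. Rows run north to south; indices are 1-based in R. Nodata is
propagated, never imputed: every downstream count, cross-tabulation and
carbon total excludes nodata cells. Non-square cells are rejected so
the cell area `A = cell_size² / 10⁴ ha` is unambiguous. I/O is ESRI
ASCII grid, chosen so that every fixture in the test suite is plain
readable text; the format carries the full metadata contract
(dimensions, origin, cell size, nodata) and round-trips bit-exactly.

## Reclassification

The bundled table maps the 44 CORINE level-3 grid codes (1–44 in
standard order) onto targets 1–7 (Settlement, Crop land, Forest land,
Grassland, Wetland, Water body, Other land), fixed in that order so
transition matrices and pool tables are comparable across runs. CORINE
distributions vary between 3-digit codes and 1–44 grid codes, so the
table is an input (`read_reclass_map()`), not a constant. The standard
CLC name "Bare rocks" is used for the bare soil/rock class. Unmapped
codes either stop the run or become nodata with a reported count;
under the strict policy reclassification conserves the number of valid
cells and hence total area.

## Transition estimation

Per-period matrices are estimated by cross-tabulating consecutive maps
and row-normalising: `P_ij = n_ij / n_i·`, the maximum-likelihood
estimate of a first-order, time-homogeneous Markov chain. Two choices
deserve note:

* **Empty rows become identity rows.** A class absent at the period
  start has no data; treating it as "persists if it reappears" keeps
  matrix products and quantity projections defined. Any other
  convention would inject mass invisibly.
* **Averaging across periods is an unweighted arithmetic mean.** The
  mean of row-stochastic rows is row-stochastic, so no renormalisation
  is involved. Averaging over three six-year periods damps single-period
  anomalies at the cost of assuming stationarity.

Matrices are serialised at full precision; the bundled averaged matrix
is printed at 4 decimal places (rows sum to 1 within ±0.0015) and is
renormalised on read, with adjustments capped at 1 % before the file is
considered corrupt.

## CA–Markov prediction

The Markov chain fixes quantities; the cellular automaton places them.

* **Quantities.** `n' = nᵀP`, rounded to integers conserving the total
  by largest-remainder rounding. The six-year step is applied once, not
  compounded per iteration.
* **Suitability.** For each cell and target class,
  `P[current, c] · (ε + f_c)`, where `f_c` is the class-c fraction in
  the 5×5 neighbourhood (edge-truncated, nodata excluded) and
  `ε = 0.01` keeps transitions into locally absent classes possible.
  These are exactly the two ingredients of the classical formulation:
  transition probabilities and a contiguity filter. Richer suitability
  drivers (roads, slope) are out of scope.
* **Iterations.** Six by default — one per projected year. Class quotas
  are interpolated linearly from current counts to the Markov targets
  across iterations, so change accrues gradually and each intermediate
  map is a valid landscape.
* **Allocation.** Greedy over all (cell, class) claims in descending
  suitability, under per-class quotas. Ties favour persistence, then
  lower row-major index, then lower class code, making the default run
  fully deterministic; a seeded random tie-break is available. Cells
  whose transition row is degenerate (stay-probability 1) are frozen
  first, so absorbing classes never lose cells. After the final
  iteration the per-class counts equal the Markov targets exactly, and
  the total valid-cell count is conserved by construction.

Commercial implementations of this model family differ in their
allocation internals and are not reproduced bit-for-bit; the properties
the tests pin down are quantity exactness, identity-matrix fixpoint,
determinism under a fixed seed, and spatial coherence (the predicted
map clusters more than a random relabelling with identical counts).

## Map validation

Agreement between a simulated and a reference map is decomposed after
Pontius (2000, 2002). From confusion-matrix proportions with simulated
marginals `c` and reference marginals `r`: observed agreement
`M = Σ p_ii`, nominal chance `N(n) = 1/J`, expected agreement of a
quantity-informed random allocation `N(m) = Σ c_j r_j`, and the maximum
agreement achievable given the quantities `P(m) = Σ min(c_j, r_j)`.
The seven components (chance, quantity, stratum, grid-cell agreement;
grid-cell, stratum, quantity disagreement) always sum to 1. The kappas
are

* `Kno = (M − N(n)) / (1 − N(n))`
* `Kstd = (M − N(m)) / (1 − N(m))`
* `Kloc = (M − N(m)) / (P(m) − N(m))`
* `Klocstrata` — within-strata location kappa; with a single stratum
  (the only case implemented; a strata raster is accepted nowhere in
  the bundled study) it equals `Kloc` exactly.

Two numerical choices: degenerate denominators (`N(m) = 1`, or
`P(m) = N(m)`, e.g. single-class maps) yield `NA`, not a number. And
because the component decomposition clamps at zero when observed
agreement falls below expectation, the exact `M`, `N(m)`, `P(m)` are
carried as attributes when components are computed from a confusion
matrix, so kappas remain exact (and can be negative) in that regime;
components supplied manually from a published table reconstruct the
intermediates from the components themselves, which is exact whenever
agreement exceeds chance, as in every published case here.

The nominal chance level defaults to `1/8`, not `1/7`: the bundled
published decompositions print "agreement due to chance 0.1250",
i.e. the upstream validation tool counts a background category
alongside the seven map classes. `J_chance` is an explicit argument
everywhere.

## Carbon pools

Densities are Mg/ha per class for four pools: above-ground (CAG),
below-ground (CBG), soil (CSOIL) and dead organic matter (CDOM).

* **Forest** pools scale growing stock (GS, m³/ha — 225.4 for the
  bundled study) through biomass expansion factor, wood basic density,
  carbon fraction, root-to-shoot ratio, and mortality:
  `BAG = GS·BEF·WBD`, `CAG = BAG·CF`, `CBG = BAG·R·CF`,
  `CDOM = CAG·(AMR + litter_fraction)`. Note the below-ground formula
  includes R — below-ground biomass is defined as `BAG·R` — even though
  abbreviated writeups sometimes omit it. The litter share of CDOM is a
  configurable fraction of CAG (default 0) because the regression the
  bundled study's inventory used is not published.
* **Grassland**: IPCC defaults, `CAG = 2.7·0.5`, `CBG = 2.7·4.0·0.5`,
  no CDOM.
* **Crops and wetland**: unweighted means over type rows (five woody
  crops; six wetland types).
* **Settlement, water, other land**: literature constants.

The bundled pool table is authoritative for assessment: its forest row
(CAG 93) is an inventory-calibrated value that the mean-factor equation
chain does not reproduce (it gives ≈82.3, and deadwood-only CDOM ≈1.5
vs the table's 9). The per-species averaging order and litter model
behind the published row are not recoverable, so the equations are
provided for methodological reuse and deliberately not forced to match
the table.

## Assessment and valuation

Storage is `A · (CAG+CBG+CSOIL+CDOM)` per cell, summed over valid
cells; an equivalent class-aggregate route (`Σ area_km2 · 100 ·
density`) serves published area tables and doubles as a two-route
consistency oracle (equal to 1e-9 relative for any raster).
Sequestration is the signed storage difference; CO₂ equivalence is
exactly 44/12. The discounted value of a period's change spreads the
sequestration evenly over the period's years and discounts each annual
increment: `V·s/(q−p) · Σ_{t=0}^{q−p−1} [(1+r/100)(1+c/100)]^{−t}`,
with defaults V = 200 EUR/Mg C (a 60 EUR/t CO₂ price), r = 3 %/yr,
c = 0 %/yr. With r = c = 0 this reduces to `V·s`. The ledger reports
both the discounted and the undiscounted value, because published
period values in this literature do not always state which convention
was applied; for the bundled study the printed period values sit
between the two (≈0.999·V·s), so neither is forced to match and both
are exposed. Monetary columns are carried at full precision; 2-decimal
million-EUR rounding is presentation only.

## Synthetic landscapes

The generator exists so every stage runs and is testable with no
external data; its defaults are the study conditions, not tuning knobs.

* **Initial map**: `n_patch_seeds` (default 50) random seed cells — the
  first J carrying one class each, guaranteeing presence — and a
  nearest-seed (Voronoi) tessellation with exact integer
  squared-distance ties broken by lowest class code. This yields a
  patchy, autocorrelated map with roughly equal class shares.
* **Dynamics**: each cell draws its successor from the transition row
  of its class (default matrix: the bundled Calabria average, so the
  synthetic dynamics are the study's estimated dynamics). With
  probability `spatial_mixing` (default 0.25) the draw is re-weighted
  to classes present in the 3×3 neighbourhood, clustering change;
  `spatial_mixing = 0` gives exact marginal dynamics and is the setting
  under which the estimation stage provably recovers the generating
  matrix (200×200 grid, ≈5,700 cells per class: binomial sampling error
  ≲0.006 per entry, against the 0.02 acceptance bound).
* **Seeding**: a single integer seed; step k of a series uses
  `seed + k`, so each raster is independently reproducible.

What the generator does *not* emulate: real geomorphology, class-size
imbalance as extreme as real Calabria (wetland is 0.01 % of the real
landscape but ≈1/7 of the synthetic one), mapping error, and
minimum-mapping-unit effects. Passing the synthetic recovery test shows
the estimator is consistent under the model's own assumptions — not
that six-year CORINE snapshots satisfy them.

## Scale and determinism of the shipped checks

The test suite runs at sizes from 2×2 hand cases to a single 200×200
four-date series (seconds in total); the pipeline smoke tests use 30×30
series. All randomized suites use fixed seeds; the CA–Markov default
configuration is deterministic by design, so reruns are byte-identical.

## Known limitations

* One-stratum validation only; `Klocstrata` is `Kloc` by construction.
* The CA allocator is a faithful member of the CA–Markov family, not a
  bit-level reproduction of any particular commercial tool.
* First-order, stationary Markov dynamics; no driver covariates.
* No reprojection or resampling: rasters must already be aligned.
* Soil carbon is an inventory input, not modelled.
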