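---
title: "Methods: entropy-weighted ecosystem health assessment with spatial diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-weighted ecosystem health assessment with spatial diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehiscape)
```

## The assessment problem

Karst rocky-desertification regions are ecologically fragile: thin soils over
carbonate bedrock erode quickly, so land-use change, climate and human
pressure translate into rapid shifts in ecosystem condition. County-scale
monitoring in such regions typically combines three ingredients, and
`ehiscape` implements all of them as one tested pipeline:

1. a **Pressure-State-Response (PSR)** indicator system condensed into a
   composite **Ecosystem Health Index (EHI)** with entropy-derived weights;
2. **spatial autocorrelation diagnostics** (global Moran's I and local LISA
   cluster typing) of the county-level index;
3. **driver attribution** by geographically and temporally weighted
   regression (GTWR) after variance-inflation-factor screening.

The package also ships a synthetic-data generator so that every stage can be
exercised, and its statistical behavior verified, without access to any
proprietary raster archive.

## PSR indicators

Eight indicators enter the index, one per column of the zone-by-year panel:

| layer | indicator | orientation | source |
|---|---|---|---|
| pressure | POP (population) | negative | zone attribute |
| state | NDVI | positive | zone attribute or band math |
| state | SHDI, SHEI, COHESION | positive | land-use raster |
| response | ESV | positive | land-use raster x coefficient table |
| response | CONTAG, FRAC_MN | positive | land-use raster |

The five landscape metrics are computed from the categorical raster directly
(no external Fragstats run is needed). Conventions, all configurable where
they are genuinely choices:

* **Patch delineation** uses 8-neighbor connectivity by default (the common
  Fragstats setting); perimeter is counted in cell edges and scaled by the
  cell size when map units matter. Nodata cells belong to no patch but do
  expose the perimeter of their neighbors.
* **SHDI** is `-sum(p_i log p_i)` in nats with `0 log 0 = 0`; **SHEI** is
  SHDI/log(m) over the m classes present, and is defined as 0 for a
  single-class landscape (there is no evenness to measure; the limit is
  otherwise undefined).
* **COHESION** is the landscape-wide patch-cohesion form
  `100 (1 - sum p / sum p sqrt(a)) / (1 - 1/sqrt(Z))`. It is 0 when every
  patch is a single cell and undefined on a single-cell landscape (error).
* **CONTAG** uses the class-adjacency entropy form with double-counted cell
  adjacencies in the four cardinal directions; it errors on a single-class
  landscape rather than fabricating a value. During testing we enumerated
  all 512 two-class 3x3 rasters against a brute-force oracle; one folk
  intuition fails under the standard formula and is therefore *not* asserted
  anywhere: the checkerboard is **not** the CONTAG minimum (the minimum
  needs adjacency mass spread over all class pairs, which a perfect
  checkerboard forbids).
* **FRAC_MN** assigns single-cell patches fractal dimension 1 before
  averaging (the `2 log(p/4) / log(a)` form is 0/0 at one cell; a single
  cell is a square).

**ESV** is the equivalent-coefficient aggregation `sum_i A_i V_ci`. The
published per-area coefficient tables are deliberately *not* hard-coded: the
table is a required input, and the packaged
`synthetic_esv_coefficients()` - used by tests and the synthetic pipeline -
only preserves the qualitative ordering (water and forest most valuable,
construction nil). **LUI** is the area-weighted intensity grade with the
standard grade table (construction 4, arable 3, grassland 2.5, forest 2,
water 2, unused 1), bounded by [1, 4].

## Normalization, entropy weights and the index

Indicators are min-max normalized so 1 is always "healthier": positive
indicators map to `(x - min)/(max - min)`, negative ones (POP) to
`(max - x)/(max - min)`. Two printed-formula ambiguities common in this
literature are resolved the standard way: the negative-orientation form that
yields values in [-1, 0] is replaced by the equivalent `(max - x)` form
(required for the entropy logarithms to exist), and the weight normalization
divides by the sum of the difference coefficients (the only reading
consistent with weights summing to 1).

Extrema are pooled over **all zone-year observations** by default, not per
year. This is required for any statement about temporal trends in the index:
with per-year extrema every year is rescaled to its own range and levels are
not comparable. Per-year pooling remains available (`pooling = "by_year"`).

With `f_ij = Y_ij / sum_j Y_ij`, entropy `E_i = -k sum f log f`
(`k = 1/log n` over the n pooled observations), difference coefficient
`d_i = 1 - E_i` and weights `w_i = d_i / sum d`, the index is
`EHI_j = sum_i w_i Y_ij` in [0, 1]. A constant indicator normalizes to zero
with a warning and receives weight 0 rather than aborting the run. Weights
are always recomputed from the data at hand; the reference weight table
shipped in `inst/extdata/` is a consistency fixture for the criterion-layer
sums, not a default.

Grades use half-open, upward-closed bands so every value in [0, 1] receives
exactly one grade: I [0, 0.5), II [0.5, 0.55), III [0.55, 0.6), IV [0.6, 1].
The change classification for `dEHI = EHI_last - EHI_first` uses I
[0.06, 0.08), II [0.08, 0.10), III [0.10, 0.13]; values outside the band are
labelled `out-of-range` instead of being forced into the nearest level,
since nothing guarantees a new data set stays inside it.

## Spatial autocorrelation

Zone contiguity defaults to **queen** (any shared boundary point),
row-standardized; rook is available. Global Moran's I is the standard
cross-product form; inference is reported two ways, because practitioners
compare z-scores against 2.58 while permutation p-values are the robust
default:

* the analytic z-score under the randomization assumption (closed-form
  variance), and
* a seeded permutation pseudo p-value,
  `p = (hits + 1)/(n_perm + 1)`, directional toward the observed side of
  `E[I] = -1/(n-1)`.

Local Moran's I uses mean-deviates scaled by the global variance
(`m2 = sum z^2 / n`), so the LISA decomposition
`sum_i I_i = S0 * I` holds exactly (tested to 1e-10). Inference is by
conditional permutation (zone i's value held fixed, the others permuted
among its neighbors). Cluster labels H-H/L-L/H-L/L-H are assigned only where
`p < alpha`; `alpha = 0.05` is the package default for maps - a
significance-level choice, not something inherited from any particular
study.

## GTWR driver attribution

Candidate drivers are screened by iterative VIF removal (threshold 7.5,
highest first; infinite VIF - a constant or perfectly collinear column -
goes first). Which drivers survive is data-dependent by construction and is
never asserted in tests.

The local model at observation i is weighted least squares with Gaussian
kernel weights over the combined squared space-time distance
`d2 = du^2 + dv^2 + tau dt^2`, `w = exp(-d2/h^2)`. Kernel family, bandwidth
criterion and the space-time ratio are rarely printed in applied papers, so
the package adopts the canonical choices and exposes them as configuration:
Gaussian kernel; `h` minimizing AICc (leave-one-out CV optional) by a coarse
log-grid bracket plus golden-section refinement; `tau` searched on a grid
scaled by `(spatial diameter / time range)^2`, covering "time ignored"
through "time dominating". The search is deterministic; a boundary optimum
produces the best grid point with a warning. Coordinates are assumed planar
(project first; the synthetic zones are already planar), and time is encoded
as years since the first epoch, with `tau` carrying the unit conversion.

Two exact limits anchor the implementation and are tested at tolerance:
`h -> Inf` reproduces global OLS, and `tau = 0` on a single epoch reproduces
plain GWR. Local coefficient maps are binned into k = 4 quantile levels per
driver per year (the usual "four levels" of coefficient maps have no
canonical breaks; quantiles make the maps comparable across drivers), with
the coefficient sign reported separately.

## The synthetic-data generator

The generator emulates a province-scale panel: by default 88 zones on an
8 x 11 rectangular lattice (an analytically known contiguity structure,
which is what makes the spatial tests exact), 100 x 100 cells per zone, and
five epochs spanning twenty years.

* **Land cover**: per zone, a latent Gaussian random field (white noise
  convolved with a separable Gaussian kernel, correlation length
  `autocorr_range` cells) is thresholded at quantiles matching the target
  class proportions - this yields the clumped mosaics characteristic of
  karst landscapes with exact composition control. Epoch t+1 blends the
  previous field with a fresh one at weight `1 - persistence`, so land cover
  evolves gradually; `persistence = 1` with a static composition gives an
  unchanging landscape. The default composition surface drifts construction
  land up and arable land down over time with forest increasing northward,
  so composition-derived indicators vary over both space and time.
* **Drivers**: each driver is a smooth deterministic surface of the
  normalized zone centroid and epoch plus a zone-level stochastic component
  with a short correlation length (1 lattice unit, sd 1.0), redrawn each
  epoch. The short correlation length is a deliberate design choice: it
  represents idiosyncratic county-level deviation from regional gradients
  and gives local regressions within-neighborhood contrast. Without it,
  smooth drivers are locally collinear with the local intercept and *no*
  local method can recover coefficients - an identification failure of the
  design, not of the estimator.
* **Response**: `y = beta_0(u,v,t) + sum_l beta_l(u,v,t) x_l + eps` with
  `eps ~ N(0, 0.3^2)`. The default coefficient surfaces vary by roughly a
  factor of three across the domain and are bounded away from zero, so the
  sign of every effect is well defined everywhere and sign-recovery is a
  meaningful target; signs mirror the directions reported for karst systems
  (precipitation, humidity, nighttime lights positive; temperature,
  vegetation-cover fraction, slope, land-use intensity negative). The true
  coefficient matrix is returned as a separate `truth` element never written
  into the observable panel.

What the generator does **not** emulate: irregular county polygons (zones
are equal-area rectangles, so area- and count-based grade shares coincide),
remote-sensing measurement error and compositing artifacts, missing data,
and any feedback of the response onto the drivers. Tests passing on this
design therefore validate the *estimators and their contracts*, not the
substantive conclusions one would draw from real rasters.

## Numerical choices and degenerate inputs

* `0 log 0 = 0` throughout (entropy, contagion, Shannon indices).
* Grade and level boundaries are half-open and upward-closed; a sweep of
  10,001 values over [0, 1] yields exactly four grades.
* Local WLS solves use the Cholesky factor of `X'WX`; a failed or
  near-singular factorization aborts with the offending observation and the
  advice to enlarge the bandwidth.
* Quantile thresholding of the latent field uses the empirical type-7
  quantile, making realized class proportions exact up to cell
  discreteness (error `O(1/n_cells)`).
* Constant indicator columns, all-zero normalized columns, island zones,
  constant response values and all-nodata rasters all produce explicit
  warnings or errors - never silent zeros.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; pipeline reruns with the same configuration are byte-identical.

## Problem sizes used by the test suite

The suite runs the full pipeline at 16-25 zones with 20-30 cell rasters,
exhaustive metric enumeration at 3 x 3, Moran checks at 16-25 zones, and
the GTWR recovery experiment at the full default scale (88 zones x 5
epochs, n = 440, 20 replicates with the bandwidth selected once by AICc).
These sizes were chosen so the whole suite completes in well under a minute
of CPU per module while still exercising every code path at the study's
actual panel dimensions where it matters (coefficient recovery).

## Known limitations

* Landscape metrics are raster-only; vector (polygon) landscapes and
  moving-window analyses are out of scope.
* No Getis-Ord statistics or distance-band weights; contiguity only.
* GTWR is the basic local-constant form: no mixed global/local terms and no
  bootstrap bands for local coefficients.
* The ESV module treats the coefficient table as exogenous configuration;
  localizing benchmark prices to a study region is the user's
  responsibility.
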