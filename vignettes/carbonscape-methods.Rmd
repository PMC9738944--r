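---
title: "Methods: carbon bookkeeping, patch-generating simulation, and entropy weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon bookkeeping, patch-generating simulation, and entropy weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonscape)
```

carbonscape studies how land-cover change moves terrestrial-ecosystem
carbon, with the Guizhou karst province as its bundled case study. This
vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic test surface does and does not show
about real data.

## Carbon bookkeeping

Every land-cover class $i$ carries four carbon pools (Mg/hm²) — aboveground
biomass, belowground biomass, soil organic carbon, and dead organic matter —
whose sum is the class's total density:

$$C_{i,\mathrm{tot}} = C_{i,\mathrm{above}} + C_{i,\mathrm{below}} +
  C_{i,\mathrm{soil}} + C_{i,\mathrm{dead}}.$$

Carbon storage of a landscape is the area-weighted sum of total densities.
Units are fixed package-wide: densities in Mg/hm², areas in km², storage
reported in $10^4$ Mg, so

$$\mathrm{storage} = \mathrm{area}_{\mathrm{km^2}} \times C_{\mathrm{tot}} / 100,$$

since 1 km² = 100 hm² and the reporting unit absorbs the remaining $10^4$.
Densities are treated as static over time; nothing interpolates them between
epochs, which is the standard (and acknowledged) simplification of this kind
of bookkeeping. The bundled Guizhou density table keeps its published values
verbatim — including the settlement soil density (205.07 Mg/hm²) that
exceeds grassland's, which we deliberately do not "sanity-adjust".

Rounding happens only at the reporting boundary: `storage` retains full
precision, `storage_rep` rounds half-up to 2 decimals (base `round()` is
banker's rounding, which would disagree with published tables on exact
halves). Decade *differences* are computed between the 2-decimal reported
totals, because that is how differences of published tables are formed.

The per-cell change map between two epochs is expressed in Mg **per cell**
(density difference × cell area × 100), so its matrix sum equals the
landscape storage delta exactly, with no unit juggling — a property the test
suite asserts on every fixture pair.

The bundled 2050 area table stores the forest cell as missing: the published
value is internally inconsistent with its own column total and with the
published forest storage. The accessor recovers it by total-area
conservation (the 2050 total equals the 2030 total, 173,702 km²), giving
90,123 km², which reproduces the published storage of 239,420.76 × 10⁴ Mg.

## Transition accounting and agreement

`transition_matrix()` cross-tabulates aligned epoch pairs into a 6 × 6 area
flow matrix. Cells that are nodata in *either* epoch are excluded from the
tabulation — the alternative (excluding per-epoch) breaks the identity
between matrix marginals and per-epoch class areas, which we instead assert
as an invariant.

`agreement()` reports overall accuracy and Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, with $p_e$ from the confusion marginals.
The degenerate case $p_e = 1$ (both maps constant) is defined as
$\kappa = 1$ if the maps are identical and $0$ otherwise. The published
validation figures for the real Guizhou rasters (kappa 0.76, overall
accuracy 0.83) depend on data this package does not ship; correctness here
is pinned instead by a hand-worked 10-cell confusion oracle (OA 0.7,
kappa 0.4) and by property tests (label-permutation invariance,
chance-level kappa for independent maps).

## Markov demand

Future per-class area demand is a first-order Markov projection: the
observed flow matrix is row-normalised into a transition-probability matrix
$P$ (empty rows become identity rows so absent classes stay absent), and
demand after $n$ steps is $a^\top P^n$. One step spans the observed decade,
so a 2030 projection from a 2010→2020 chain is one step and 2050 is three.
Two open points were decided as follows:

* Demand for later horizons chains the Markov *vectors* (map-independent)
  rather than re-estimating from simulated maps — simpler, reproducible, and
  consistent with reusing a single observed chain.
* Integer cell targets use largest-remainder rounding, so targets sum
  exactly to the valid cell count and the automaton can stop at tolerance 0.

## Land-expansion analysis (LEAS)

For each class $k$, expansion cells (not $k$ at $t_0$, $k$ at $t_1$) are
positives and never-$k$ cells are negatives; both are subsampled at
`sampling_rate` (default 0.01) and a random forest (20 trees; mtry 9 when at
least 9 drivers exist, otherwise two-thirds of the driver count) is trained
on a 1:1 balanced sample, then predicted over all valid cells to give the
class's development-probability surface. Probabilities are the forest's
class-vote fraction with no recalibration, matching common
patch-generating-simulation practice; driver contributions are normalised
impurity importances. Choices made where practice varies:

* Negative sampling is uniform over never-$k$ cells, matched 1:1 with the
  positives — balanced classes stabilise the probability calibration.
* Classes with fewer than 20 positives or negatives are skipped with a
  warning and receive a flat 0.5 surface rather than an unstable fit.
* Driver layers are put in canonical (alphabetical) order before fitting, so
  results are invariant to how the stack was assembled.
* Fits are single-threaded with a fixed seed; thread count is a performance
  knob that must not change results.

Per-class neighbourhood ("domain") weights can be derived as each class's
share of total off-diagonal flow (summing to 1), or supplied verbatim. The
published Guizhou vector (farmland 0.1470 … other 0.0001) sums to 0.4258 and
matches no recoverable normalisation of the flows, so it is reproducible
only as a given vector; both paths are implemented.

## The patch-generating automaton (CARS)

The simulator allocates demand by iterated local competition. Each round,
for every cell of an over-demand class and every under-demand class $k$
permitted by the 0/1 transition mask:

$$\mathrm{OP}_k = P^{\mathrm{dev}}_k \times \Omega_k \times w_k,$$

where $\Omega_k$ is the fraction of class-$k$ neighbours in the
`neighborhood_size` window (default 3, centre excluded, truncated at edges,
nodata excluded) and $w_k$ the domain weight. Where $\Omega_k = 0$, a
spontaneous-seed path fires with probability
`expansion_coeff × seed_fraction` (defaults 0.5 and 0.05) and proposes
$\mathrm{OP}_k = P^{\mathrm{dev}}_k\, w_k\, U(0,1)$ — this is what lets new
patches nucleate away from existing ones. A roulette wheel over the
candidate classes picks one proposal per cell, and the conversion is
accepted if its OP clears a global threshold $\tau$.

Published descriptions of this mechanism fix the two coefficients and their
qualitative meaning but not the numerics, so the package commits to:

* $\tau$ starts at the 90th percentile of first-round OP values and is
  multiplied by `patch_decay` (default 0.5) after any round that leaves
  unmet demand — the "threshold-decreasing mechanism" that lets easy,
  well-seated conversions happen first.
* Accepted conversions are capped per target class at its remaining deficit
  and per source class at its remaining surplus (highest OP first), so
  demand is never overshot, over-demand classes never gain cells, and the
  stopping rule is exact at `demand_tolerance = 0`.
* Allocation within a round is order-free (vectorised over cells), removing
  scan-order bias; all randomness flows from one `rng_seed`.
* `seed_fraction` applies per round, not over the whole run.

Infeasible demand under the mask (an under-demand class with no permitted
donor) is detected up front and reported by class name. The case-study mask
freezes aquatic and settlement cells, the usual constraint that water bodies
and construction land do not convert away.

`run_projection()` composes the whole chain; later horizons start from the
previous simulated map while their demand chains the Markov vectors.

## Entropy-weight scoring

Region-by-indicator tables are standardised per indicator orientation
(positive: larger is better), the standardised shares give each indicator an
information entropy $S_j = -\frac{1}{\ln n}\sum_i R_{ij}\ln R_{ij}$ (with
$0\ln 0 := 0$), and weights are $W_j = (1-S_j)/\sum_j(1-S_j)$: indicators
that differentiate regions more weigh more. Scores are
$E_i = \sum_j S_{ij} W_j \in [0,1]$.

Two literal variants are preserved because published write-ups of this
method sometimes state them: a standardisation with the orientations swapped
(`form = "as_printed"`, the mirror image $1-S$), and a score over raw values
(`basis = "as_printed"`, scale-dependent). The defaults follow the
conventional orientation, which matches the verbal definition of a positive
indicator and makes scores affine-invariant per indicator — an invariant the
tests assert. Shares $R_{ij}$ are computed from *standardised* values; raw
values would make the entropy scale-dependent. Degenerate inputs follow
logged conventions: constant columns standardise to 0.5, all-zero columns
get entropy 1, and an all-entropy-1 table falls back to equal weights with a
warning. Score banding for display uses quantile classification (4 bands by
default).

## The synthetic test surface

Because no deposited rasters exist for the case study, the package generates
its own study conditions, and these defaults *are* the tested conditions:

* **Landscapes** are smoothed Gaussian noise thresholded at class-fraction
  quantiles — the simplest neutral-landscape mechanism with a controllable
  clustering scale. Class shares default to the Guizhou 2020 composition
  (farmland 0.2742, forest 0.5283, grassland 0.1771, aquatic 0.0068,
  settlement 0.0134, other 0.0002); realised shares are exact to one cell by
  largest-remainder assignment. Default grids are 200 × 200 (fixture
  benchmarks) and 60 × 60 (replicated recovery runs) at 1 km² per cell.
* **Drivers** are class-dependent mean shifts plus smooth unit-variance
  noise; a shift of ~2 standard deviations makes the planted direction
  recoverable (point-biserial r well above 0.3), a shift of 0 gives a null
  driver.
* **Evolution** plants exact conversion counts, scaled from the observed
  decade's province-wide flows (e.g. farmland→forest 1649 km² of
  176,098 km² total), placed deterministically on the highest-affinity
  source cells so stage tests have exact expectations; stochastic placement
  exists behind a flag.
* **Seeds are explicit everywhere**; generators are pure functions of their
  arguments and never touch global RNG state.

What passing on this surface shows: the bookkeeping, flow accounting,
demand projection, suitability recovery, allocation and scoring machinery
are correct, deterministic and mask-compliant under realistic class
compositions and planted, recoverable structure. What it does not show:
karst geomorphology, real driver collinearity, classification error in the
input rasters, or the published kappa/accuracy of the real-data simulation —
those require the original rasters, which is why the real-data validation
figures are documented as context rather than asserted.

The LEAS defaults keep the published 0.01 sampling rate; the synthetic
fixtures call `extract_expansion()` with `sampling_rate = 1` because 1% of a
few hundred expansion cells would fall below the 20-sample minimum — a
fixture-size matter, not a change to the method's defaults.

## Known limitations

* Rasters are read and written as ESRI ASCII grids; the georeference header
  is carried through untouched and no reprojection or resampling is
  implemented — inputs must be pre-aligned (`align_check()` enforces this).
* Single-scenario simulation only; no ecological-protection constraints or
  multi-scenario demand.
* Carbon densities are first-level (6-class) and time-invariant; no
  valuation, sequestration rates, or 25-type densities.
* City-level sustainability scores of the case study are not reproducible:
  the underlying 9-city indicator values were never published (only
  max/min/sd per indicator), so the scoring module is validated on synthetic
  tables and hand-worked oracles instead.
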