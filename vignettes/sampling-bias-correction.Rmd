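---
title: "Evaluating sampling-bias corrections for presence-only SDMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sampling-bias corrections for presence-only SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Occurrence records harvested from opportunistic databases are rarely a
uniform sample of a species' range: observers cluster near cities and
roads, some regions are systematically surveyed while neighbours are not,
and range cores attract more attention than peripheries. A species
distribution model (SDM) trained on such data learns the survey pattern as
much as the niche. `sdmbias` provides a complete, self-contained testbed
for asking *how much* a given geographic sampling bias damages a
presence-only SDM and *which correction method best recovers the model
that unbiased data would have produced*.

The package works entirely on a synthetic landscape and a virtual species,
so every experiment is reproducible from a seed with no data download.
Real occurrence CSVs (`species,lon,lat`) and ESRI ASCII predictor grids
plug into the same functions.

## Study design

The factorial experiment degrades an unbiased occurrence set with four
bias mechanisms, each at three intensities, with replication:

| Bias type | Mechanism | Intensity knob (low / medium / high) |
|---|---|---|
| `two_areas` | full retention north of the occurrence-latitude midpoint, constant retention south of it | p_s = 0.5 / 0.2 / 0.05 |
| `gradient` | retention linear in latitude, 1 at the northernmost record down to p_min at the southernmost | p_min = 0.5 / 0.2 / 0.05 |
| `center` | Gaussian decay `exp(-d² / 2σ²)` of great-circle distance d to the occurrence centroid, σ = s · (max centroid distance) | s = 0.6 / 0.4 / 0.2 |
| `travel_time` | retention = accessibility^γ, concentrating records near cities | γ = 1 / 2 / 4 |

Records are thinned by independent Bernoulli draws against the retention
surface (`apply_bias()`), the simplest mechanism consistent with a
per-record retention probability; the excluded records are kept as test
presences for AUC. The intensity table is a package calibration — chosen
once to span mild to severe thinning while keeping at least 20 records
from a 2000-record sample — and is exposed via `bias_spec(params = )` for
recalibration. Scenarios that fall below 20 retained records are rejected
rather than silently modeled.

Five published corrections are applied to every biased sample, each
reducing to a *plan* (training records + background weights/mask +
combine rule) handed to the engine:

1. **Systematic sampling** — one random record per 2° lattice cell
   (0.2° is the conventional choice for narrow-extent datasets). The
   lattice is anchored at the raster's lower-left corner so runs are
   reproducible; the anchor is otherwise arbitrary.
2. **Bias file** — a Gaussian kernel density surface of the records,
   rescaled to exactly [1, 20], used as background sampling weights.
3. **Restricted background** — background drawn only within a 500 km
   (great-circle) buffer of the records (100 km for narrow extents).
4. **Cluster** — records thinned in *environmental* space: PCA on their
   standardized continuous predictors, Ward-linkage hierarchical
   clustering on all axes, the tree cut at k = ⌈n/2⌉, one random record
   per class. Ward linkage and the ceiling convention for odd n are
   package choices; the source procedure specifies only Euclidean
   distances and "half of the occurrences".
5. **Split** — records split at the median occurrence latitude (the split
   line is a package choice), one model per stratum over the full study
   area, composite map = per-cell maximum. Strata under 5 records abort
   the scenario rather than merging silently.

## The suitability engine

The engine is **not MAXENT**: it is an L1-penalized logistic regression
discriminating presences from background points (via `glmnet`), with
standardized continuous predictors, optional quadratic terms, and one-hot
categorical levels. Its logistic output in [0, 1] honors the same
contract as MaxEnt's logistic format, and MaxEnt's bias-file option is
emulated by weighted background *sampling* (selection probability
proportional to weight), which is close to, but not provably identical
to, MaxEnt's internal weighting. All corrections and metrics interact
with the engine only through `sample_background()` / `fit_sdm()` /
`predict_sdm()`, so a different engine with the same three contracts can
be swapped in through `sdm_engine()` without touching anything else.

Two numerical choices matter:

* **Fixed penalty.** `lambda = 0.01 × regularization_strength` on
  standardized features. Small enough to recover a planted monotone
  signal (map-to-signal Spearman ρ > 0.5 in the test suite), large
  enough that presences drawn from the background distribution yield a
  near-flat map (max − min < 0.2).
* **Class-balanced observation weights.** Presences and background carry
  equal total weight regardless of their counts. Without this, thinning
  a 2000-record sample to ~90 records (systematic sampling at 2°)
  mechanically inflates the penalty-to-likelihood ratio and flattens the
  map, so record-reducing corrections would be punished for their *size*
  rather than judged on the environmental *distribution* they retain —
  an artifact MaxEnt avoids by scaling its regularization with sample
  size. With balanced weights the fitted surface depends on where the
  presences sit in environmental space, not on how many there are.

Background points (default 10000) are placed at cell centers, sampling
cells with replacement; prediction is nearest-cell with no interpolation,
and points on an internal cell boundary belong to the cell to the
north/east (half-open cells), making point-in-cell tests unambiguous.

## Evaluation

Four metrics compare each biased/corrected model with the unbiased
reference model (fitted once per species on the full dataset):

* **AUC** in Mann–Whitney form, `(#{p > a} + ½#{p = a}) / (n_p n_a)`,
  using the *excluded* records as test presences and 10000 evaluation
  absences — true absences sampled outside the virtual species' range
  mask, or plain background points for real data. The unbiased model's
  reference AUC comes from 5 seeded random splits, each held out in
  turn. The implementation is verified against a brute-force trapezoidal
  ROC oracle.
* **D_geo** — Schoener's D between suitability maps: normalize each map
  to sum 1 over shared valid cells, `D = 1 − ½Σ|p_a − p_b|`.
* **D_env** — Schoener's D in environmental space (PCA-env): PCA on the
  standardized continuous predictors of *all* valid cells, 500 points
  sampled from each model's map with suitability as sampling weight
  (cells with replacement), both clouds kernel-smoothed on a 100 × 100
  lattice spanning the cell-score range (Gaussian product kernel,
  Silverman bandwidth per axis) and compared with the same D formula.
  The occupancy ("availability") correction of the original PCA-env
  procedure is not applied; densities are of the sampled points
  themselves.
* **G_over** — overlap of binary maps thresholded at the 10th-percentile
  training-presence suitability (threshold = the (⌊0.1 n⌋ + 1)-th
  smallest training-presence value; off-by-one conventions differ between
  implementations, so the rule is pinned down in `binarize()`). The
  overlap statistic is the Jaccard index |A∩B| / |A∪B| — the source
  procedure never defines its binary overlap; Jaccard is symmetric,
  bounded in [0, 1], and strictly geographic.

Correction performance is the standardized improvement
`Δ = (m_corrected − m_biased) / (m_unbiased − m_biased)`, one Δ per
metric: 1 is perfect correction, 0 no change, negative values mean the
correction made things worse. When unbiased and biased metrics coincide
within 1e-9 the index is undefined and reported as `NA` (excluded from
means and ranks), not an error. For the three overlap metrics the
unbiased reference is 1 by definition (a model against itself).

`run_species_design()` orchestrates the factorial, `summarize_results()`
aggregates replicate means and flags corrected (mean Δ > 0) and
best-in-cell methods, and `rank_methods()` ranks methods within each
(type × intensity) cell — rank 1 best, ties averaged — and averages
ranks across the 12 cells.

## The synthetic landscape

`generate_landscape()` emulates, at desk scale, the layer roles of a
continental modeling exercise: a north–south gradient layer, four
spatially autocorrelated climate-like fields (Gaussian-smoothed white
noise, standardized), a land-cover-like categorical layer
(quantile-binned autocorrelated field, five equal-frequency classes), and
an accessibility surface (max over 8 random cities of exp(−d/15 cells))
standing in for a travel-time map. The default grid is 120 × 100 cells of
0.25°, i.e. a 30° × 25° extent. The virtual species' truth is one
land-cover class (~20% of cells); 2000 unbiased records are drawn
uniformly over that class, mirroring the virtual-species construction the
framework is designed to test.

Deliberate consequences of this construction:

* The truth is defined by a single categorical layer the model also
  sees, so the engine separates presences from outside-range absences
  almost perfectly and AUC saturates near 1 for unbiased *and* biased
  models; ΔAUC is then frequently undefined. The overlap metrics carry
  the discriminating signal, which is why the experiment's primary index
  is ΔD_geo.
* What the synthetic tests *do* show: the relative behavior of the five
  corrections under controlled, known bias on a stationary landscape.
  What they do *not* show: performance under real climate structure,
  range boundaries shaped by history rather than habitat, or biases
  other than the four mechanisms simulated.
* Scale matters for the restricted-background method. A 500 km buffer is
  ≈ 4.5° of latitude; around even a few dozen scattered records it
  covers a large share of a 30° × 25° extent, so restricting background
  to the buffer binds far less than on a continental (90° × 55°) domain
  where occurrences occupy a small fraction of the area. At this extent
  the split method's composite (per-cell max of two stratum models)
  inflates suitability the most, and the acceptance suite documents that
  it — not restricted background — takes the worst mean ΔD_geo rank,
  while systematic sampling consistently ranks best and restricted
  background never corrects. Users studying the restricted-background
  pathology specifically should enlarge the landscape or shrink
  `buffer_km` in proportion to their extent.

## Problem sizes

The shipped tests run the full 4 × 3 design with 3 replicates on the
default 120 × 100 landscape (36 biased datasets, 216 model-evaluation
rows) in well under a minute, and the remaining suites on 60 × 50
landscapes; these sizes were chosen so the whole suite iterates quickly
during development while still exercising every code path at realistic
record counts (600–2000 presences, 2000–10000 background points).
Replication at the full 10 replicates is a single argument change.

## Known limitations

* The engine's linear+quadratic feature set is fixed; MaxEnt's automatic
  feature-class selection (hinge/threshold features, sample-size-dependent
  regularization) is out of scope, so absolute metric values differ from
  MAXENT-based studies by construction even where the rankings agree.
* Coordinates are plain geographic degrees; no projections, and
  great-circle distances use a spherical Earth (haversine, R = 6371 km).
* Method combinations (split + thinning, biasfile after thinning, ...)
  are not orchestrated, though `correction_plan()` composes manually.
* D_env's 500 map points are sampled with replacement; sampling without
  replacement is not offered.
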