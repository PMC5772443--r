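---
title: "Contrasting presence-only suitability models with plot-based abundance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting presence-only suitability models with plot-based abundance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Natural history collections (NHCs) are the dominant occurrence source for
presence-only species distribution models, but they are not a random draw
from a species' abundance distribution: collectors work along access
routes, over-collect rare species and under-collect common ones, and the
records themselves carry georeferencing defects (missing fields,
zero/centroid/capital coordinates, duplicates, misidentifications).
Forest-inventory plots measure something different — local relative
abundance, `RA = n_i / N`, the stems of a focal species over all stems in
a census — and interpolating plot abundances gives a range estimate that
does not depend on environmental covariates at all.

`sdmabund` implements both estimators on a common half-degree grid and
the statistics that confront them, plus a synthetic study system with
known ground truth so every stage has an acceptance surface. The package
is organised as an analysis workflow: the numbered scripts under
`analysis/` narrate the stages, and every computation they perform lives
in package functions exercised by the test suite.

## The two models

**Abundance side.** `idw_surface()` interpolates plot relative abundance
by inverse distance weighting: a cell's estimate is the weighted mean of
the nearest `k_max = 150` plots within `d_max = 3` degrees, with weights
`w_k = d_k^{-1/2}`. Both defaults follow the plot-interpolation
convention for Amazonian tree inventories, where the 3-degree limit
(~300 km) encodes dispersal limitation: with no plot inside that radius
the species is predicted absent. "Square-root-of-distance" weighting is
read as the inverse exponent `p = 0.5` — a literal `w = sqrt(d)` would
up-weight distant plots, contradicting the interpolation's purpose; the
exponent is configurable for anyone wanting the conventional `p = 2`.
Coincident plots short-circuit to their mean, making the interpolator
exact at plot locations. The binary range map is `RA > 0` (strictly)
inside forest; naturally non-forested cells are excluded.

**Suitability side.** `fit_maxent()` is a deliberately minimal
maximum-entropy model: a Gibbs distribution `q(x) = exp(lambda . f(x)) / Z`
over background cells, with features restricted to each climate variable
and its square (product, threshold and hinge classes are excluded on
biological grounds), maximising

```
(1/m) sum_presences lambda . f(x)  -  log Z(lambda)  -  sum_j beta_j |lambda_j|
```

with `beta_j = c * s_j / sqrt(m)` (`s_j` the presence standard deviation
of feature `j`, floored at 1e-4; multiplier `c = 1` by default). This
replaces the per-feature-class interpolation tables of the reference
implementation with one transparent schedule — those tables are
undocumented fitting heuristics, and a single multiplier keeps the
estimator well-posed and tunable. The optimiser is accelerated proximal
gradient ascent (FISTA) with backtracking and a monotonicity safeguard:
an extrapolated step that fails to improve the penalised objective
restarts the momentum, so the recorded objective trace is non-decreasing
— a contract the tests check. Convergence is declared when the objective
gains less than `tol = 1e-7` (default; tightened to 1e-12/1e-13 where
tests compare against closed forms).

The background is sampled uniformly without replacement from the *bias
file* — the binary layer of cells holding at least one cleaned collection
of any species — so that background reflects survey effort (target-group
background). Logistic output uses the standard entropy calibration
`l(x) = e^H q(x) / (1 + e^H q(x))` at prevalence 0.5, a strictly
monotone transform of `q`; ranks, and therefore AUC, are unaffected by
the choice.

## The cleaning pipeline

`clean_pipeline()` is a two-step filter with a fixed precedence order so
each removed record reports exactly one reason:

1. **Deterministic geo-validation** — `MISSING_GEO` (longitude, latitude
   *or locality* absent), `LAT_EQ_LON` (exact equality, nonzero),
   `ZERO_COORD` (both exactly zero; a single zero coordinate is a
   legitimate meridian/equator point), `CAPITAL`/`PROVINCE_CENTROID`
   (within 0.05 degrees of a gazetteer point — a sub-cell snap radius
   typical of centroid-assignment artefacts), `COUNTRY_MISMATCH` (only
   when country polygons are supplied). Then `DUPLICATE_CELL`: one record
   per species per half-degree cell, keeping the lowest record id.
2. **Kernel-density outlier removal** — a fixed-bandwidth Gaussian KDE of
   the species' point pattern, evaluated at each record; records below an
   empirical quantile of those densities are removed. The quantile
   depends on regional spread: species occurring in 1–3 of the six
   regions use `0.05`, wider species `0.01`, preserving the principle
   that an aggressive threshold on a widespread species would amputate
   genuine occurrence clusters. Neither the bandwidth nor the quantile
   values are dictated by the method, so all three are configuration:
   the 1.0-degree default bandwidth (~two grid cells) keeps the density
   local while bridging adjacent occupied cells.

Two properties matter and are tested: the deterministic stages have
perfect recall and zero false positives on labelled synthetic
corruptions, and re-running the pipeline on its own output removes
nothing further at the deterministic stages. A structural limitation
worth knowing: the KDE stage can remove at most roughly the quantile
share of a species' records, so when the outlier rate exceeds the
quantile (as for the injected 3% misidentification rate against the 1%
wide-species quantile), recall at the cohort level is necessarily
partial. The dedicated fixture test shows the filter does its job when
outliers are rarer than the quantile; the cohort-level shortfall is a
property of quantile thresholds, not of the implementation.

## Comparison statistics

* `null_model_test()` — 99 models fitted to `n` cells drawn without
  replacement from the bias-positive cells (`n` = unique presences),
  identical background and settings; the observed training AUC must rank
  95 or higher among the 100 (ties take the lowest rank, which is
  conservative). Sampling nulls from surveyed cells rather than the
  whole grid is what makes the test bias-corrected; a flag restores
  whole-grid nulls for comparison. Calibration is verified by
  simulation: presences drawn from the bias distribution itself are
  flagged at well under the nominal 5%.
* `glm_collection_vs_abundance()` — binomial GLM of the per-cell
  collection indicator on interpolated abundance over forested study
  cells; "positive relationship" means slope > 0 with Wald p < 0.05.
  Complete separation is flagged rather than hidden.
* `spearman_suit_vs_abundance()` — midrank Spearman rho between
  suitability at plot localities and the plots' abundance, each plot one
  observation even when several share a cell. The *observed* plot
  abundance is used by default (an exact-interpolating surface returns
  the plot's own value at the plot anyway); a switch to the interpolated
  value at the plot's cell is a one-liner for anyone wanting the other
  reading.
* `quantile_reg_90()` — linear 90th-percentile quantile regression by
  check-loss minimisation: IRLS on the smoothed loss, then an exact
  polish over candidate lines through low-residual sample-point pairs
  (an optimum of the piecewise-linear loss lies on such a line; the
  tests compare against full pair enumeration). Confidence intervals and
  p-values come from a pairs bootstrap (200 replicates, percentile
  interval, doubled one-sided p) — a generic resampling scheme chosen
  over a specialised Markov-chain marginal bootstrap because the
  contract is simply a slope interval.
* `collinearity_screen()` — pairwise Spearman over valid cells with
  greedy elimination at `|rho| > 0.7` (drop the variable with the most
  over-threshold partners; ties by larger mean |rho|), plus the PCA
  loadings table for the manual relevance choice that remains out of
  scope.
* Range summaries — convex hull of cleaned records buffered by 3 degrees
  (the same dispersal scale as the interpolation; degrees and km are
  equated as the study system does, with an optional fixed 111.32 km/deg
  conversion), cell-center point-in-polygon clipping, area of occupancy
  as a 1-cell count, and cell-level sensitivity in both directions (the
  abundance map scored against collection localities, the suitability
  map against plot presences).

All distances everywhere are Euclidean in degree space — the convention
of the study design this package follows — so none of the geometry
applies a great-circle correction; at Amazonian latitudes the distortion
is a few percent and affects both models identically.

## The synthetic study system

`gen_world()` emulates exactly the moving parts the pipeline must
survive, at a scale chosen for fast, repeated end-to-end runs:

* **Grid**: 60 x 60 half-degree cells (a 30 x 30 degree Amazonia-scale
  window), six rectangular regions, a forest mask with two savanna-like
  holes.
* **Environment**: six layers named after familiar bioclim variables,
  each a low-order trend plus smoothed noise scaled to [0, 1], with two
  layer pairs constructed to exceed |rho| = 0.7 so the collinearity
  screen always has work to do.
* **Species**: 15 species with Gaussian niche responses on one or two
  layers; abundance is suitability times a dispersal kernel around 1–4
  population centers, zeroed outside three kernel radii, cell-maximum
  normalised to 0.05 (a hyperdominant-like ceiling: even dominant
  Amazonian trees rarely exceed a few percent of stems). Odd-indexed
  species are narrow (clamped to their three highest-mass regions),
  even-indexed wide — both branches of the KDE quantile rule are always
  exercised.
* **Plots**: 400 one-hectare censuses at ~550 stems (Poisson), stem
  counts multinomial in the cell's true abundances with an explicit
  "other species" pool absorbing residual mass. 400 plots on 3600 cells
  reproduces the sparse-but-informative coverage regime of the real plot
  network (1675 plots on a far larger grid).
* **Collections**: per-cell sampling intensity is accessibility (a
  distance-decay field around random polylines — rivers and roads) times
  `RA^0.5`; the exponent below one over-represents low-abundance areas,
  which is precisely the collectors' bias the GLM is meant to detect,
  while keeping the relationship weakly positive so the comparison
  statistics have non-degenerate behaviour. Collection cells are drawn
  without replacement per species, so cell-level duplicates exist only
  where injected — that is what makes "recall 1, false positives 0"
  well-defined for the deduplication filter. Errors are injected at
  configured rates (5% missing fields, 2% zero coordinates, 2% lat=lon,
  3% + 3% gazetteer snaps, 10% duplicates, 3% misidentifications), each
  record carrying its ground-truth label; misidentified records are
  relabelled to a species whose range lies more than 2.5 degrees away,
  so they are genuine spatial outliers for the KDE stage.

What the generator does *not* emulate: realistic floristic composition,
temporally explicit collecting, taxonomic noise beyond outright
misidentification, topography or non-climatic environmental structure.
Passing tests therefore certify the machinery — the filters remove what
they claim, the estimators recover known truth, the tests hold their
nominal size — not that any particular real-world dataset satisfies the
models' assumptions.

## Numerical choices and degenerate inputs

* Half-open cell intervals with a lower-left origin; a point on a shared
  edge belongs to the cell whose lower edge it sits on. Grid
  registration is configuration, never inferred from data.
* Rasters travel as ESRI ASCII grids (nodata −9999), the plain-text
  dialect every GIS reads; round-tripping preserves values and mask.
* Empty plot tables interpolate to an all-zero surface with a warning;
  a species with fewer than two records skips the KDE stage; fewer than
  five presence cells skips the model with a logged gate; a constant
  abundance predictor or constant suitability vector is flagged as
  degenerate rather than fitted.
* The 10% training-presence threshold is the largest value `t` with at
  least 90% of training presences at or above `t`, so binarisation drops
  at most the lowest decile of presences; with a single presence the
  threshold is its value.
* Cohort runs are deterministic end to end: per-species seeds are fixed
  offsets from the master seed, and the acceptance test reruns the whole
  demo and compares JSON byte-for-byte.

## Problem sizes

The shipped demo (60 x 60 grid, 15 species, 400 plots, ~6,500 records,
99 null models per species, 200 bootstrap replicates) completes in a
couple of minutes on one core; the labelled-corpus checks use a 22-species
world with ~11,000 records; calibration simulations use 100 replicates at
a reduced background (300 cells). These sizes were chosen so the full
suite can be run habitually — the statistical conclusions they support
(exactness, calibration, recovery) are scale-free properties.

## Known limitations

* The KDE quantile bounds removals, as discussed above.
* Degree-space distances ignore latitude-dependent cell area; fine for a
  contrast of two models sharing the convention, wrong for absolute
  range areas near the poles.
* The minimal maximum-entropy model recovers suitability well only when
  the species' niche axis (or a strong proxy) survives the collinearity
  screen — dropping a variable that is itself the niche axis costs rank
  fidelity in the tails, visible in the recovery tests.
* Area-of-occupancy counts are cell counts on a geographic grid, not an
  equal-area standard.
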