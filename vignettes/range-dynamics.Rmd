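---
title: "Ensemble range dynamics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble range dynamics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangedyn)
```

## The problem

Given presence records of a species and stacks of environmental predictors
under a current and one or more future scenarios, we want (i) a habitat
suitability map per scenario, (ii) a binary potential range per scenario, and
(iii) summary indices of how the range changes between scenarios. When many
species are analysed under a common scheme, the per-species indices can be
averaged and compared across scenarios, and the binary ranges can be overlaid
to map where risk accumulates.

The quantities at the core of the package are defined from the binary range
decomposition. With `SR` the area occupied under both scenarios (stable
range), `expansion` the future-only area and `contraction` the current-only
area:

* `RCS = SR + contraction` — range size under the current scenario,
* `RFS = SR + expansion` — range size under the future scenario,
* `RRI = RFS / RCS` — range ratio index; `RRI > 1` means net expansion,
* `RSI = 2·SR / (RCS + RFS)` — range similarity index, a Sørensen-type
  overlap in [0, 1]; low values mean the range *moved*, whatever happened to
  its size.

Areas are spherical cell areas on a 6371-km sphere,
`R²·Δλ·(sin φ_top − sin φ_bottom)`, so high-latitude cells count for less;
indices are computed from unrounded areas and rounded only for reporting
(ratios of rounded areas generally do not reproduce a ratio computed at
pixel level).

## The modelling pipeline

`run_pipeline()` chains the stages for each species:

1. **Occurrence cleaning.** Records with coordinate uncertainty above 5 km
   are dropped (strictly greater-than; unknown uncertainty is kept), and the
   rest are greedily thinned to a 10-km minimum great-circle separation in a
   seeded random visiting order. Greedy thinning is one of several published
   conventions; it is maximal (no dropped point could be re-added) and
   reproducible given the seed.
2. **Pseudo-absences.** A surface range envelope (per-predictor presence
   quantiles at `q = 0.025` and `1 − q`) defines "inside the species'
   climate"; pseudo-absences are sampled uniformly from land cells outside
   the envelope in at least one predictor, excluding presence cells. 1000
   pseudo-absences are drawn when there are fewer than 1000 presences,
   otherwise as many as there are presences.
3. **Predictor selection.** Importance is permutation-based: the preliminary
   model is fitted once, then each predictor column is shuffled
   (`n_permutations = 5`) and the importance is the mean of
   `1 − cor(ŷ_full, ŷ_shuffled)`, clipped at zero. Pearson correlations
   among predictors are then screened at `|r| > 0.7`: repeatedly, the
   currently largest correlated pair loses its lower-importance member
   (ties drop the later code in canonical order). The preliminary model is a
   classification tree by default: an unpenalized logistic preliminary model
   is vulnerable to quasi-separation against envelope-based pseudo-absences,
   which inflates coefficients on every predictor and spreads spurious
   importance over layers the species never responds to; tree predictions
   are sparse in the predictors, so irrelevant layers score essentially
   zero.
4. **Ensemble fitting.** Each requested algorithm is evaluated with five
   seeded label-stratified random 70/30 splits (the commonly stated
   "five-fold cross-validation with a 70/30 split" is internally
   inconsistent — five folds imply 80/20 — and the repeated-split reading is
   the convention of the ensemble platforms this design follows). On each
   split the AUC is computed on held-out scores and the TSS at the held-out
   MSS threshold. Algorithms with mean TSS > 0.6 *or* mean AUC > 0.8
   (strict inequalities) enter the ensemble with weights proportional to
   their raw mean TSS; the included members are refitted on the full table
   for projection.
5. **Projection and binarization.** The ensemble map is the per-cell
   weighted mean of member suitabilities. The binary range uses the MSS
   threshold — the smallest observed score maximizing sensitivity +
   specificity under "present iff score ≥ τ" — computed from the ensemble's
   scores at the presence and pseudo-absence locations under each scenario's
   projection. By default the threshold is recalibrated per scenario
   (matching analyses that report scenario-specific thresholds); with
   `threshold_mode = "current"` the current-scenario threshold is reused.
   Recalibration is the right default when the training locations remain
   representative; for strong planted shifts it can collapse (the training
   sites lose suitability, dragging the threshold to ~0), which is why the
   switch exists and the planted-shift check below uses it.
6. **Dynamics and overlays.** Per species × future scenario, the binary
   ranges are decomposed into stable/expansion/contraction areas and the
   indices above. Across species, binary ranges are overlaid by simple
   addition, suitability maps are summed into total-suitability surfaces,
   and future minus current totals give increased/decreased-area bookkeeping
   (zero-delta cells count to neither side). Scenario summaries report mean
   RRI/RSI (2 decimals), top-5 rankings, and two-sided paired t-tests on
   per-species values for requested scenario contrasts; identical vectors
   give `t = 0`, and constant non-zero paired differences are reported as
   infinite `t` with `p = 0` rather than an error.

### The algorithm registry

Six families are implemented behind a common `fit`/`score` interface:
`sre` (inside-envelope fraction of predictors — also the pseudo-absence
envelope), `glm` (logistic regression with linear + quadratic terms, so
bell-shaped responses are representable), `gam` (penalized splines via
mgcv), `cart` (rpart classification tree), `xgb` (boosted trees), and
`proto` (nearest prototype in standardized predictor space, logistic in the
centroid-distance difference). Other names commonly used by ensemble
platforms (`rf`, `gbm`, `mars`, `fda`, `maxent`, `maxnet`, `ann`, `ct`) are
accepted as aliases of the closest implemented family, with a logged notice.
Bit-compatibility with any specific platform is not a goal; weights,
screening and thresholds are defined above, not borrowed.

## The synthetic world

Because the real occurrence compilations and global predictor datasets
cannot be redistributed, the package ships a virtual-species world whose
statistical structure mirrors what the pipeline assumes:

* **Predictor stacks** (`make_env_stack()`): 31 layers — 19 bioclimatic
  (B1–B19), 9 anthropogenic-disturbance (8 land-use fractions + population
  density), 3 topographic — generated as white noise convolved with a
  Gaussian kernel (default autocorrelation length 5°) and standardized to
  mean 0, SD 1 over land. Layers are kept on this standardized scale rather
  than rescaled to physical units: every downstream statistic (correlations,
  quantile envelopes, areas, indices) is scale-free, and niche parameters
  are easiest to reason about in landscape SDs. Requested predictor pairs
  are remixed after orthogonalization so their sample correlation over land
  is *exactly* the target — this exercises the `|0.7|` pruning rule
  deterministically.
* **Bioclimatic variables** (`bioclim_from_monthly()`): the standard 19
  summaries from monthly temperature and precipitation, with quarters
  defined as the 12 wrap-around consecutive 3-month windows selected by
  precipitation sum or mean temperature, ties to the earliest start month,
  and sample (n−1) standard deviations. `B15` uses `100·sd/(1 + mean)`.
* **Virtual species** (`virtual_species()`): Gaussian responses
  `exp(−(x−opt)²/(2·breadth²))` multiplied across niche predictors, passed
  through a logistic link `plogis(slope·(raw − midpoint))`. The reference
  community (`make_demo_world()`) draws 2–3 niche predictors per species
  from the climate + anthropogenic pool, optima uniform in ±1.2 SD and
  breadths in 0.5–0.8 SD, link slope 15, midpoint 0.5. Optima are kept
  within the commonly observed range deliberately: a species whose optimum
  is essentially absent from the landscape has a truncated, unrecoverable
  niche, and no presence/pseudo-absence method can be expected to rank
  algorithms sensibly there. The topographic "aspect" layer never enters a
  niche, providing a known-irrelevant predictor for importance checks.
* **Sampling** (`sample_occurrences()`): cells drawn with probability
  proportional to true suitability (times an optional effort layer), points
  at cell centers; thinning then deduplicates repeated cells.
* **Scenarios** (`make_future_scenario()`, defaults in `make_demo_world()`):
  additive/multiplicative shifts of selected layers. The four reference
  scenarios shift the temperature-linked bioclim layers coherently by
  +0.35/+0.5 SD (mild) or +1.1/+1.3 SD (severe), the severe pair also drying
  the precipitation layers and raising urban fraction — two "forcing levels"
  × two "model patterns", emulating the usual 2-pathway × 2-GCM design.

What the synthetic world does *not* emulate: sampling bias correlated with
accessibility, coordinate error, non-Gaussian or interacting niche
responses, dispersal limitation, and real GCM spatial structure. Green tests
therefore certify the *machinery* — metrics, thresholds, areas, indices,
bookkeeping, determinism — and the recoverability of well-posed niches, not
predictive skill on real species.

## Study sizes and numerical choices

The bundled experiments use grids of 50×70 to 100×100 one-degree cells,
300–400 presences per species and 5 evaluation splits — small enough that
the full 15-species × 5-scenario experiment runs in well under a minute,
large enough that held-out TSS ≈ 0.75–0.85 and truth correlations ≈ 0.9,
the regime the method expects on real data. Other conventions:

* Thresholding uses `score ≥ τ`; candidate thresholds are the observed
  scores, tie-break to the smallest, so thresholds are deterministic.
* AUC is the exact Mann–Whitney statistic via midranks (ties count ½).
* Evaluation splits are stratified by label; a degenerate single-class side
  triggers a reseeded resplit (up to 10 attempts).
* `RRI` is reported missing with a warning when `RCS = 0`, `RSI` when both
  ranges are empty.
* Rasters are stored as ESRI ASCII grids (plain text, cell-center
  registration, row 1 northernmost); values round-trip to ~1e−6, and
  indices are computed in double precision throughout.
* All stochastic stages take explicit seeds; a pipeline run records its
  settings, seeds and output checksums in a manifest, and rerunning with the
  same seed reproduces identical dynamics tables.

## The planted-shift check

A single-predictor, warm-adapted species (optimum 22 °C, breadth 3 °C on a
temperature layer scaled to 15 ± 5 °C) is fitted under the current scenario
and projected onto a uniformly +2 °C warmer one. Because the optimum sits on
the warm tail of the landscape, warming opens formerly-too-cold terrain that
is more abundant than the terrain lost, so the true range expands
(`RRI > 1`) while shifting (`RSI < 1`). The model's RRI is compared with the
analytic ratio of true-suitability super-threshold areas at the model's own
threshold; with the `glm + cart` ensemble and current-threshold reuse the
two agree within a few percent. This is the package's end-to-end correctness
probe: it couples sampling, fitting, projection, thresholding and the area
arithmetic against a quantity computable without any model.

## Known limitations

* The greedy thinning and greedy pruning orders are conventions, not unique
  solutions; both are seeded/deterministic and documented rather than
  optimal.
* Ensemble weights use raw TSS; members entering via the AUC branch with low
  TSS receive correspondingly low (possibly near-zero) weight.
* Pseudo-absences are shared across algorithms within a species, not
  regenerated per algorithm.
* The envelope-based pseudo-absence rule requires enough candidate cells
  outside the envelope; tiny grids abort with an explicit shortfall error
  rather than degrading silently.
* GeoTIFF is not read or written; the raster interchange format is the ESRI
  ASCII grid.
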