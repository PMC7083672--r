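---
title: "Comprehensive habitat suitability modelling with TSS-weighted ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive habitat suitability modelling with TSS-weighted ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Species distribution models (SDMs) relate georeferenced occurrence records
to gridded environmental layers and predict, cell by cell, how suitable a
landscape is for the species. `chsdm` implements a complete
*comprehensive habitat suitability* (CHS) workflow of the kind used for
narrowly distributed alpine plants: a multi-algorithm ensemble SDM driven
by climate and terrain, gated afterwards by two biotic layers — a
categorical soil suitability model and a binary vegetation mask — and
projected onto future climate scenarios with zonal area accounting.

The pipeline stages are:

1. **Occurrences and pseudo-absences.** Presence records are cleaned
   (complete coordinates only, exact duplicates collapsed, out-of-extent
   points dropped). True absences are unavailable, so background
   "pseudo-absence" points stand in: the background region is the convex
   hull of the occurrences buffered by 200 km of great-circle distance,
   minus presence cells; three replicate sets of 500 cells are drawn
   uniformly without replacement.
2. **Predictor screening.** Candidate variables are reduced by a greedy
   Pearson screen guided by PCA: while any pair has |r| at or above the
   threshold (default 0.80), the member of the worst pair with the
   smaller share-weighted PCA loading is dropped. Aspect is circular and
   is screened through its cosine/sine encoding.
3. **Single models.** Ten algorithms — ANN, CTA, FDA, GAM, GBM, GLM,
   MaxEnt, MARS, RF and the surface range envelope (SRE/BIOCLIM) — are
   fitted on each pseudo-absence replicate with equal total class
   weighting (each absence weighs `n_presence / n_absence`), over ten
   repeated stratified 70/30 splits. Three replicates x ten algorithms x
   ten repeats gives 300 scored runs.
4. **Evaluation.** Each run's held-out predictions are scored by the true
   skill statistic, `TSS = sensitivity + specificity - 1` with
   `sensitivity = a/(a+c)` and `specificity = d/(b+d)`, maximized over a
   0.00–1.00 threshold grid in steps of 0.01, and by the rank-based
   (Mann–Whitney) AUC with tie correction and case weights.
5. **Ensemble.** Algorithms whose mean TSS falls below 0.5 are excluded
   wholesale (in the motivating use case this removes SRE, leaving
   h = 270 runs). The remaining runs are combined per cell as a convex
   combination `BT_i = sum_j w_j x_ij` with TSS-proportional weights
   `w_j = r_j / sum_k r_k`.
6. **Habitat overlay.** Soil suitability `S` comes from a categorical
   maximum-entropy model (below); vegetation is binarized to `V` (1 on
   the configured habitat classes). The three-class CHS rule is:
   unsuitable when `V = 0` or `BT < 0.3` or `S < 0.3`; suitable when
   `V = 1` and both `BT >= 0.5` and `S >= 0.5`; marginally suitable
   otherwise. Boundary values follow the printed `>=` convention, so
   `BT = S = 0.5, V = 1` is suitable and `BT = S = 0.3, V = 1` marginal.
7. **Scenario projection.** The fitted runs are projected (not refitted)
   onto each future GCM x RCP climate stack; per-RCP maps are unweighted
   means over GCMs, and the final per-period map is the unweighted mean
   over RCPs. Soil, vegetation and topography are held fixed, reflecting
   that soil and vegetation change lags climate change.
8. **Reporting.** Spherical per-cell areas
   (`R^2 * dlambda * (sin(lat_top) - sin(lat_bot))`, R = 6371 km) feed
   per-zone, per-class area and percentage tables, class-transition
   cross-tabulations between periods, evaluation-strip response curves
   with suitable ranges above a 0.3 probability cutoff, and
   shuffling-based variable importance.

## The categorical soil MaxEnt

For a single categorical predictor the presence-background
maximum-entropy solution collapses to per-category relative occurrence
rates — the ratio of presence frequency to background frequency. We add
Laplace smoothing (one pseudo-count per category on both presence and
background counts) so sparse and unseen categories get finite scores, and
map ratios to [0, 1] with the logistic output `S = ratio / (ratio + 1)`:
a category used exactly in proportion to its availability scores 0.5,
over-used categories approach 1. Model quality is reported as held-out
AUC over ten replicate 75/25 presence splits against the background; the
final scores are fitted on all presences. The soil background is the same
buffered-hull region used for pseudo-absences, keeping the
presence/background geography consistent across the two models.

## The synthetic world and virtual species

Real inputs for this kind of analysis (30-arc-second bioclim layers,
national soil and vegetation maps, curated occurrence records) cannot be
bundled, so the package generates a synthetic study system with the
statistical structure the analysis assumes; every stage is exercised on
it in the tests.

* **Continuous fields** are Gaussian random fields: white noise smoothed
  by a separable Gaussian kernel (correlation length in cells,
  default 6), restandardized, then placed on physically sensible scales.
  Temperature-like layers (`bio1`, `bio10`, `bio11`) carry a latitudinal
  gradient (−1.1 °C per degree of latitude) and an elevational lapse
  (−0.4 °C per 100 m); precipitation-like layers (`bio12`, `bio19`) are
  clipped nonnegative; `bio4` and `bio15` are seasonality-like fields.
  Elevation averages 3000 m with an 800 m field, and slope/aspect are
  derived from it by Horn's eight-neighbour finite differences (aspect in
  compass degrees, flat cells flagged −1).
* **Categorical mosaics.** Soil classes are quantile bins of an
  independent autocorrelated field; vegetation classes are quantile bins
  of elevation plus noise, so vegetation bands track elevation and the
  virtual species' habitat vegetation is spatially coherent. Classes 4–6
  of six are treated as habitat by default, mimicking high-elevation
  forest, shrubland and meadow.
* **Virtual species.** Suitability is a product of Gaussian responses
  `exp(-(x - mu)^2 / (2 sigma^2))` — smooth, unimodal and recoverable,
  matching the bell-shaped response curves the ensemble is expected to
  produce. The default niche is deliberately temperature-driven: `bio1`
  optimum 8 °C with sd 2 (in the cold tail of the landscape, so uniform
  warming shrinks the pool of cold-enough cells), `bio4` optimum 7.3 with
  sd 1.5, and a weak `bio12` response (optimum 800 mm, sd 400). These
  values were fixed when the generator was designed and are not tuned.
* **Occurrences** are distinct cells drawn with probability proportional
  to suitability; the default count is 99, matching the motivating
  study's record count, while parameter-recovery experiments use 200.
* **Scenarios** are spatially uniform per-layer deltas: end-of-century
  warming of 1.0/1.8/2.2/3.7 °C for RCP2.6/4.5/6.0/8.5 (2050s at 60 % of
  the 2070s signal), a fixed −0.3/0/+0.3 °C inter-model spread, and
  precipitation scaled by +3 % per degree — CMIP5-like magnitudes chosen
  for realism, not downscaled model output.
* **Zones** are near-equal rectangular blocks (quadrants for four zones),
  standing in for administrative regions in the area reports.

What the generator does *not* emulate: anisotropic or nonstationary
spatial covariance, geodesically exact random fields, realistic pedology
or phytogeography, observation bias in occurrence records, and spatially
structured climate change. Tests passing on this world therefore
demonstrate that the machinery is correct and that the pipeline can
recover a known niche under clean conditions — not that any particular
real-world map is right.

## Numerical and design choices

* **Cell convention.** A cell contains its top and left edges; points on
  the bottom/right extent edge are outside. Extraction and
  occurrence-to-cell mapping share this convention.
* **Threshold convention.** A point is predicted positive iff its score
  is `>=` the threshold; TSS threshold ties break toward the lower
  threshold.
* **"Bootstrapping" repeats** are repeated random stratified 70/30
  splits (the held-out 30 % is the test set), not resampling with
  replacement.
* **Per-run weighting.** Eq. `w_j = r_j / sum(r)` is applied to the
  retained *runs* (e.g. 270 of them), not to per-algorithm means, and
  the ensemble sum runs over those same h runs. Runs with nonpositive
  TSS would receive negative weights and are dropped with a warning.
* **Learner mapping.** All outputs are clipped to [0, 1]: tree ensembles
  and CTA via class probabilities, ANN via a logistic output unit, GLM
  and GAM (thin-plate smooths, k = 4) via the binomial link, MaxEnt as a
  lasso-penalized presence-background logistic regression on linear and
  quadratic features (glmnet, fixed light penalty 0.001), and SRE as the
  per-variable presence-quantile envelope (default 2.5 % tails)
  predicting strictly 0/1. Two learners have no maintained R
  implementation matching their classical form here, so the package
  provides them directly: FDA is realized as optimal-scoring linear
  discriminant analysis with equal class priors (its linear-basis special
  case), and MARS as an additive piecewise-linear hinge-basis logistic
  regression with fixed knots at the 1/3 and 2/3 quantiles of each
  predictor. Hyperparameters are fixed, documented defaults throughout;
  no tuning is performed.
* **Case weights** are honoured wherever the underlying fitter supports
  them (GLM, GAM, CTA, RF via `case.weights`, GBM, ANN, MARS, MaxEnt);
  FDA uses equal class priors, which is what the equal-total weighting
  achieves at class level; SRE is presence-only.
* **Response-curve anchoring.** The evaluation strip varies one variable
  while pinning the others at fixed values. The function's default
  anchor is each variable's median over valid cells, but the pipeline
  anchors at the medians of the presence records: when a species
  occupies one tail of the landscape (as the default virtual species
  does by design), a landscape-median anchor pins the dominant variable
  at an unsuitable value and the strip degenerates to near-flat noise,
  whereas presence anchoring — the convention MaxEnt-style response
  plots use — keeps the profile inside the occupied niche and the curve
  identifiable. Curves are medians-of-the-sample profiles, not averaged
  partial-dependence surfaces.
* **Failure handling.** A learner that fails to converge is flagged and
  excluded, reducing h, rather than aborting the protocol.
* **Seeds.** One master seed; every stage and replicate derives its own
  stream via a stable string hash, so whole-pipeline runs are
  bit-reproducible and individual stages are independently replayable.
* **Degenerate inputs.** Fewer than three non-collinear occurrences
  collapse the hull buffer to point buffers; constant variables yield an
  empty response curve with a warning; zero-variance columns make the
  Pearson screen report undefined correlations rather than guessing.
* **Open points resolved as follows.** The buffered hull includes its
  interior (not only the buffer annulus). The suitable CHS class
  additionally requires `V = 1` even though the printed suitable-class
  definition mentions only `BT` and `S` — the CHS index is an
  intersection with the vegetation gate, and the species grows only in
  the listed vegetation types. Occurrences falling on NoData cells are
  dropped with a message. Future-period ensembles project current fits
  (standard SDM transfer); no refitting is described or implemented.

## Problem sizes

The default synthetic study system is a 100 x 100 grid of 0.1° cells
(about 10° x 10° at the latitudes used). The full protocol at that size —
300 single models, ensemble, overlay and two projected periods — is what
`scripts/acceptance.R` runs. The package tests exercise the same protocol
end to end at the default grid for the parameter-recovery checks and on
smaller grids (20 x 20 to 50 x 50 cells) for the per-module oracles,
sizes chosen to keep the suite quick while leaving every code path
covered. Projection in the test run uses a reduced scenario matrix (two
RCPs x two GCMs); the acceptance script averages all four RCPs over a
two-model spread.

## Known limitations

* Ensemble uncertainty (e.g. coefficient-of-variation maps) and
  committee averaging of binarized maps are out of scope; the ensemble is
  the single TSS-weighted mean.
* The variable screen ships with a conventional 0.80 cutoff; the
  original analysis did not publish its exact PCA criterion, so exact
  reproduction of its nine-variable choice is not claimed — that set is
  available as `default_predictors()`.
* Raster I/O is deliberately minimal: ESRI ASCII grids (plus CSV/YAML
  sidecars). There is no reprojection; all layers must already be
  co-registered, and this is enforced to 1e-9 in the transform.
* Great-circle geometry uses a spherical Earth (R = 6371 km); at the
  hundreds-of-kilometres scale of the buffers the ellipsoidal error is
  immaterial.
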