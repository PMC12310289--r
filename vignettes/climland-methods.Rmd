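---
title: "Separating climate and land cover in species range models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating climate and land cover in species range models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`climland` asks a simple question with an awkward statistical core: when a
species' range shifts under environmental change, how much of the signal
belongs to climate, how much to land cover, and how much cannot be told
apart because the two covary in space? This vignette documents the models,
the tunable parameters, the synthetic world used for validation, and the
numerical and design choices a maintainer would want to know about.

## The modelling pipeline

### Data model

All gridded inputs live on a regular geographic (lon/lat) grid
(`env_grid`): square cells of `res_arcmin` arcminutes, upper-left origin,
half-open extent, cell-center coordinate convention. The predictor registry
distinguishes the climate set (`tmin`, `tmax` in degrees C, `pan` in mm,
`pcv` as a coefficient of variation in (0,1)), the land-cover set (six
percentage layers summing to 100 per cell: needleleaf, broadleaf,
grassland, shrub, crop, urban), and a sampling-effort (`bias`) surface in
[0,1]. Rasters are read and written as single-band ESRI ASCII grids — the
environment provides no GeoTIFF reader, and the plain-text format carries
the same georeference (origin, cell size, nodata) for the geographic grids
used here. Reprojection is out of scope; a non-geographic raster is
rejected with an error.

Cell areas are spherical: for a row with latitude bounds
$[\phi_b, \phi_t]$ and cell width $\Delta\lambda$ (radians),
$A = R^2\,\Delta\lambda\,(\sin\phi_t - \sin\phi_b)$ with $R = 6371$ km.
No ellipsoid is used; at the scales involved the difference is far below
decision relevance. Centroid displacement uses the haversine great-circle
distance on the same sphere.

### From occurrences to a weighted training table

A species is present in a cell if at least one record falls in it
(half-open point-in-cell assignment; duplicates collapse). Observation
effort is approximated by a Gaussian kernel density of (family-level)
records evaluated at cell centers and rescaled by its maximum; the
bandwidth defaults to 10 cells at the working grain — the source procedure
names no bandwidth, so ours is an explicit, configurable stand-in.
Pseudo-absences are drawn uniformly without replacement from all cells of
every biome that holds at least one presence, excluding presence cells
(standard practice; it avoids label conflicts), capped at 10,000. A single
pseudo-absence set per species is reused by every model of that species.
Presences carry weight 1 and pseudo-absences weight
$n_{pres}/n_{abs}$, making the weighted prevalence exactly 0.5.

### Component models and the ensemble

Three techniques are fitted on the same table and averaged without
weights:

* **GLM** — weighted binomial logistic regression on linear and quadratic
  terms of every predictor plus the linear bias covariate, reduced by
  backward–forward stepwise AIC. Each linear and quadratic term is
  independently droppable (no hierarchy constraint — the common default in
  stepwise software); the bias term is the scope's lower bound and is
  never dropped. Predictors are standardized internally with *weighted
  population* moments, which makes the fit exactly invariant to
  duplicating rows with proportionally split weights.
* **Random forest** — a probability forest of 500 regression trees on the
  0/1 response, each grown on a weight-proportional bootstrap sample,
  `floor(sqrt(p))` features per split, minimum node size 5. No R forest
  package is available in the target environment, so the forest is a
  small, deterministic Rcpp implementation; the hyper-parameters are our
  own fixed choices and are documented rather than inherited.
* **MaxEnt-like** — an L1-penalized logistic regression (glmnet) on
  linear, quadratic and pairwise-product features of the standardized
  predictors, the penalized-likelihood formulation of MaxEnt. The penalty
  is the 5-fold cross-validated deviance minimizer (`lambda.min`, folds
  fixed by seed); the bias feature is unpenalized so it always remains a
  control. Note that `lambda.min` shrinks true-zero coefficients heavily
  but does not always zero them exactly; tests assert shrinkage, not
  blanket exclusion.

Projections fix the bias covariate at its training maximum, so maps
describe an exhaustively surveyed world rather than the observed effort
pattern.

### Deviance partitioning

Four weighted binomial GLMs are fitted per species: bias-only (the null),
climate+bias, landcover+bias, and both+bias, each non-null model reduced
by stepwise AIC. With explained-deviance fractions
$D_M = (\mathrm{dev}_{null} - \mathrm{dev}_M)/\mathrm{dev}_{null}$,
the two-set decomposition is

$$a = D_{CL} - D_L,\qquad b = D_{CL} - D_C,\qquad c = D_C + D_L - D_{CL},$$

independent climate, independent land cover, and the joint (confounded)
share, with $a+b+c = D_{CL}$ holding exactly by construction. Percentages
are taken over $D_{CL}$. Two deliberate choices:

* The null is the *bias-only* model, not the intercept-only model: the
  comparison model of interest already absorbs effort.
* With exactly two predictor sets, the "every possible model" incremental
  scheme reduces to this three-model decomposition (up to stepwise
  reduction), so no ordering average is needed.

Because the three stepwise searches are independent, the reduced full
model can end a whisker *above* a component model in deviance (AIC trades
deviance for parsimony). Such violations surface as small negative
components and are reported as-is — truncating them at zero would hide a
useful diagnostic. Violations beyond 0.01 of explained fraction abort with
an error, since they indicate a failed fit rather than stepwise slack.

### Evaluation

* **Continuous Boyce index**: 101 moving windows of width one tenth of the
  background prediction range; per window, the presence-to-background
  frequency ratio F; the index is the Spearman correlation of F with the
  window midpoint. Windows without background mass are skipped, not
  imputed. Because windows are binned in value space, the index is only
  approximately invariant under monotone rescaling of predictions.
* **AUC** via the rank-sum (Mann–Whitney) identity, ties counting one
  half.
* **TSS** = sensitivity + specificity − 1 at the 5% omission threshold:
  the empirical 5% quantile of presence predictions, linear-interpolation
  convention (type 7). Specificity uses the pseudo-absence/background
  sample; an external presence set can be supplied wherever presence
  predictions are accepted.
* **Variable importance**: shuffle a column, re-predict, score
  $1 - \max(0, r)$ with $r$ the Pearson correlation between original and
  shuffled predictions; mean over repetitions (default 3), deterministic
  given the seed.

### Decoupled projection and range metrics

For each scenario, three prediction modes isolate the drivers: `both`
(future climate and land cover), `clim` (future climate, present land
cover) and `land` (present climate, future land cover); all other layers
always come from the present grid. By construction, a mode whose changing
set is actually unchanged reproduces the current suitability map
bit-identically — this is tested, not assumed.

The per-species omission threshold is computed once from the current
prediction at presence cells and reused unchanged for every future map, so
areas are compared against a fixed reference rule. Area of habitat is the
spherical-area sum over threshold-exceeding cells; the range centroid is
the suitability-weighted mean of cell-center coordinates with *no*
cell-area weighting (the definition is a plain weighted mean of
coordinates); shifts are great-circle distances. All metrics can be
recomputed after restricting the map to currently occupied cells, the
dispersal-limited reading of the same projections.

### Cross-species comparison

Paired Wilcoxon signed-rank tests compare each metric between prediction
modes within a scenario and between scenarios (including current) within a
mode. Zero differences are dropped (Wilcoxon's convention; Pratt's is
available), the null distribution is exact for effective $n \le 25$
without ties and a tie-corrected normal approximation otherwise. Raw
pairwise p-values are reported, matching common practice for this design;
a Holm adjustment is provided but off by default. Per-species z-scores
across the compared cells are exported for plotting only — they never
enter the tests.

## The synthetic world

Real inputs (global occurrence archives, interpolated climatologies,
land-cover projections) are deliberately out of scope; every stage is
instead exercised on virtual species with known truth.

* **Climate fields** are Gaussian random fields: white noise smoothed with
  a Gaussian kernel of scale `correlation_length` (default 5 cells),
  affinely rescaled to mid-latitude (Iberian-like) climatologies — `tmin`
  1.6 ± 2.9 °C, `tmax` = `tmin` plus a strictly positive ~28 °C offset
  field, `pan` log-normal around 674 mm, `pcv` logistic-transformed around
  0.43. Smoothing-based synthesis (rather than spectral methods) is the
  simplest adequate autocorrelation control. An optional deterministic
  meridional gradient (`lat_gradient`, °C per degree latitude) cools the
  grid northward.
* **Land cover** is a closed composition: 100·softmax over six latent
  fields, each a mixture `alpha_cov`·(fixed linear map of the standardized
  climate fields) + (1−`alpha_cov`)·(independent field). `alpha_cov`
  directly controls climate–land-cover collinearity, hence the joint
  deviance fraction downstream.
* **Virtual species** have logistic suitability on linear + quadratic
  terms of *standardized* layers (standardization keeps coefficient
  magnitudes comparable across layers and makes recovery tests
  well-posed). Occurrences are Bernoulli draws per cell with probability
  proportional to suitability times `bias^detection_gamma`, scaled to a
  target count — `detection_gamma = 0` gives unbiased sampling.
* **Scenarios** perturb temperatures additively, precipitation
  multiplicatively (with `pcv` clipped back into (0,1) under a warning),
  and land-cover *latents* (log-proportions) additively before
  re-applying the softmax, so the composition stays closed. Default deltas
  are mid-century, intermediate-emissions-sized: about +2 °C, −12%
  precipitation, cropland expansion at the expense of open habitats.

What the generator does *not* emulate: realistic biogeography, dispersal,
demography, observation error in coordinates, or circulation-model
structure (GCM names are labels on layer sets). A green test therefore
establishes that the statistical machinery recovers known structure from
data shaped like the real inputs — not that any particular real-world
inference is correct.

### Scale choices in the validation worlds

Two synthetic-world choices deserve their reasoning on record:

* **Demo gradient.** The packaged demo (`demo_config()`) models
  cool-adapted species at their warm range edge on a 50×50 grid with
  `lat_gradient = 2` °C per degree latitude. With the weaker meridional
  trend first tried (0.8), the 2.9 °C mesoscale noise dominated a single
  realization and centroid-shift directions were noise-signed; the demo is
  meant to represent a range edge where the meridional temperature trend
  (latitude plus elevation) dominates local variation, so the gradient was
  set to make that true, and the warm scenario then moves the suitable
  band poleward as intended.
* **Recovery worlds.** Deviance-partition recovery tests run on 60×60
  grids with correlation length 2 and ~700 presences. At smaller effective
  sample sizes (few, large spatial patches), *independent* smooth
  land-cover fields spuriously absorb deviance from the equally smooth
  species pattern — spatial pseudo-replication — inflating the apparent
  joint fraction even when the generating collinearity is zero. The
  chosen scale provides on the order of a thousand independent patches,
  which is the large-sample regime the recovery claims are about.

## Numerical choices

* Bilinear resampling interpolates between cell centers, edge-clamps
  outside the center hull, snaps fractional indices within 1e-9 to the
  grid (so resampling at the native resolution is the identity), and
  masks any output cell touched by a masked input with positive weight —
  the coastline rule is our choice; the source procedure does not state
  one.
* Stepwise GLM calls embed the model frame in the fitted call so
  re-evaluation during the search is self-contained; weighted binomial
  warnings about non-integer successes and saturated probabilities are
  muffled as expected artifacts, while non-convergence is an error.
* Masked cells are excluded from every sum, quantile, centroid and
  maximum.
* All randomness flows from a single root seed through named substreams
  (`seed + 1009·species_index + stage_code`, mod 2³¹−1), and every
  generator is deterministic given its seed; re-running a study with the
  same configuration reproduces byte-identical CSV outputs.
* Configurations are JSON (no YAML parser in the target environment);
  occurrence tables and all results are CSV.

## Known limitations

* Presence/background logistic contrasts estimate relative, not absolute,
  occurrence probability; recovery tests therefore check coefficient signs
  through the full grid pipeline and reserve exact (3 SE) recovery for
  directly simulated presence/absence data.
* The random forest does not extrapolate beyond the training range of a
  predictor; under strong novel climates its component predictions
  saturate where the GLM and penalized-logistic components extrapolate
  parametrically.
* The Boyce index degrades when background predictions have (near-)zero
  range, and its windowing makes monotone-transform invariance
  approximate.
* Stepwise selection makes the partition's component deviances
  path-dependent; small negative components are expected behaviour, not
  bugs.
* Only two predictor sets are supported in the partition; the alternative
  hierarchical-ordering average collapses to the same scheme here and is
  therefore not separately implemented.
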