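---
title: "Methods: imagery-derived features for tract-level outcome modelling"
author: "tractscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imagery-derived features for tract-level outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical and geometric
machinery: the model each stage implements, the assumptions behind it, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. The package computes no number quoted here that its test suite or
`scripts/acceptance.R` does not itself recompute.

## 1. The modelling problem

The target quantity is an area-level outcome rate — the motivating case is
crude obesity prevalence, in percent, for US census tracts — and the
predictor is what medium-resolution optical satellite imagery shows of
each tract's physical environment. The pipeline treats the imagery
generically: a three-band raster is tiled into fixed-size square chips,
each chip is reduced to a feature vector, and the chip-level vectors are
transferred to the tract level through an areal-interpolation step based
on pixel counting. A regression of tract rate on tract feature vector,
evaluated strictly out of sample, then measures how much outcome variation
the imagery explains.

## 2. Identifier reconciliation

Tract identifiers carry a two-digit subdivision suffix, in two dialects: a
decimal display name `XXXX.YY` and an all-digit GEOID whose last two
digits play the same role. Geography layers and outcome tables frequently
subdivide tracts differently, so both sides are normalized to a base
identifier (suffix forced to `00`), records sharing a base are dissolved,
and the two dissolved layers are matched on the base-id intersection with
an explicit report of leftovers on each side — the bookkeeping is part of
the output, not hidden.

Two decisions here:

* **Merged outcome rates** use the population-weighted mean
  $\bar w = \sum_i w_i x_i / \sum_i w_i$ over the members of a base id.
  The weighted mean is convex: a merged rate always lies within the range
  of its member rates, and equal weights reduce it to the arithmetic mean
  — both are enforced as test invariants. A missing member rate aborts the
  merge with the offending members named, rather than silently dropping
  them; silent dropping would bias the merged rate toward whatever
  subdivisions happen to be reported.
* **Dissolved geometries** are stored as multi-part polygons (the
  collection of member rings). Census subdivisions are interior-disjoint,
  so the collection *is* the union for every purpose the pipeline has:
  area, point-in-polygon tests, pixel counting. No polygon noding/clipping
  library is needed or used.

Boundary simplification for compact search geometries is classic
Douglas–Peucker, parameterized by a distance tolerance (vertex retention
is nested, so vertex count is non-increasing in the tolerance). Because
applications often prescribe a vertex budget instead of a tolerance,
`simplifyToVertexCount()` bisects the tolerance until the ring fits the
budget.

## 3. Chipping and normalization

Raster products are de-duplicated per identical footprint, keeping the
largest-area, then lowest-cloud product; any manual curation is expressed
as an explicit exclusion list so it is auditable. Pixel values are
normalized by a fixed divisor (default 10 000, the usual integer
surface-reflectance convention) with clipping at 1 — a per-image min–max
alternative exists behind a flag but is not the default, because it
destroys comparability of values across images.

The chip grid lays out $\lceil W/c \rceil \times \lceil H/c \rceil$
windows of exactly $c$ pixels (default 224, i.e. 2.24 km at 10 m pixels).
A ragged final row or column is **clamped**: the last window is shifted
inward so it ends at the image edge. Every window is therefore full-size
and inside bounds; interior windows abut without overlap and only
last-row/column windows may overlap their neighbours. Clamping was chosen
over zero-padding because padding would feed artificial black borders to
the feature extractor, and because the ceil-formula window count is then
exact for full and ragged images alike. Pixel windows are 0-based and
half-open throughout; a chip's affine transform is the parent transform
translated by the window offset.

## 4. Feature extraction

Chips are standardized band-wise, $(v - \mu_b)/\sigma_b$, with the
published ImageNet constants ($\mu$ = 0.485/0.456/0.406, $\sigma$ =
0.229/0.224/0.225) as defaults. The standardization is applied directly to
the [0, 1]-normalized reflectance values; those constants were derived for
display-range photographs, so this is a convention, not a claim of
distributional match — it is configurable per extractor spec.

The default extractor is a **deterministic surrogate**: per band it
computes mean, standard deviation, skewness, min, max, mean and standard
deviation of the gradient magnitude, and 16 block means on a 4 × 4 grid —
23 statistics per band, 69 in total — and then applies a seeded Gaussian
random projection from 69 to D dimensions (D defaults to 2048 to mirror
the penultimate-layer width of a 50-layer residual network and to exercise
the p ≫ n regime the downstream regression faces). The projection is
almost surely injective on the base statistics, so distinct chips stay
distinct; determinism means the whole pipeline is a pure function of its
inputs and seeds. A `deep` backend slot exists for substituting
pretrained-CNN activations; it deliberately errors when its runtime is
absent, instructing the caller to fall back to the surrogate, so the
package never downloads weights or requires a GPU.

## 5. Pixel-count areal interpolation

The chip↔tract link is the integer number of chip pixels falling in each
tract. A pixel belongs to a tract iff its **centre** lies inside the tract
polygon — the common rasterization convention, chosen because the counts
are then exact integers, order-independent, and reproducible by per-pixel
brute force (which the test suite does on small rasters, requiring exact
equality). Centres on a shared boundary are assigned to the tract with the
lexicographically smallest id: the implementation scans tracts in sorted
id order with a boundary-inclusive test, making ties deterministic. When
tracts partition a chip, its counts sum to exactly $c^2$.

Both aggregations are convex weighted means over those counts:

$$F_t = \frac{\sum_{c \in C} w_c F_c}{\sum_{c \in C} w_c}, \qquad
  o_c = \frac{\sum_{t \in T} w_t o_t}{\sum_{t \in T} w_t},$$

with $C$ the chips intersecting tract $t$ and $T$ the tracts intersecting
chip $c$. Note the two weights are different quantities that happen to
share a symbol in common notation: the package names them `pixel_count`
everywhere and never conflates them with the *population* weights of the
identifier-merge step. Usable chips are those fully covered by the region
boundary **and** intersecting at least one tract; the coverage test is
exact for polygons (all four corners inside, no boundary edge crossing the
open rectangle). Vector layers are expected in the raster's CRS — the
cheaper direction for pixel counting — and a CRS mismatch is an error, not
a silent reprojection.

## 6. Regression and evaluation

"Linear model" means Gaussian-identity least squares. With D ≫ n the
ordinary solution is underdetermined, so `fitLinear()` returns the
**minimum-norm pseudoinverse** solution (which interpolates the training
data) and accepts an optional ridge penalty; the intercept is never
penalized. Minimum-norm interpolation generalizes poorly when n is small
relative to D — the package exposes `ridge` precisely because users should
expect to need it in the p ≫ n regime. The random forest is a seeded
bootstrap regression forest (`ranger`) with impurity importances;
`mtry` defaults to $\lfloor\sqrt{D}\rfloor$.

Evaluation is by seeded 80/20 holdout (training size
$\lfloor 0.8\,n \rfloor$) and k-fold cross-validation (seeded shuffle,
fold sizes within one of each other, each sample tested exactly once,
pooled out-of-fold predictions). Metrics per fold are MSE,
$R^2 = 1 - SS_{res}/SS_{tot}$ and adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$.

**Effective predictors for adjusted R².** On an evaluation fold the
natural candidates for $p$ are the feature dimension (or the rank of the
training design) and the number 1. The rank-based count is degenerate
here: with D larger than the fold size, capping $p$ at $n_{test}-2$ makes
the adjustment factor $(n-1)/(n-p-1)$ explode and per-fold adjusted values
land far below −1 regardless of fit quality. Worked per-fold adjusted
values in this literature sit a few thousandths below the fold $R^2$,
which is exactly the $p_{eff} = 1$ convention — the fitted model's
prediction treated as a single derived predictor. The package therefore
defaults to $p_{eff} = 1$ and keeps the capped-rank variant available
(`pEff = "rank"`). Folds with a single test sample (k = n) or zero outcome
variance report MSE with an undefined (NA) $R^2$. Displayed metrics are
rounded to 2 (MSE) and 3 (R²) decimals; stored values keep full precision.

Feature importance averages the impurity importances over the k fold
models and rescales to percentages summing to 100; the attached
correlation is the Pearson correlation of each feature column with the
**actual** outcome (feature-vs-predicted is available behind a flag — the
two readings circulate in applied work, and the actual-outcome version is
the one that does not depend on the fitted model). Signed error is
**actual − predicted**: positive values mark under-predicted tracts. Error
tables rank tracts by signed error and emit, per configured threshold, the
subset whose absolute out-of-fold error is at least the threshold (the
"RMSE" of a single prediction being its absolute error). Out-of-fold
predictions are used so every tract has exactly one prediction from a
model that never saw it.

## 7. The synthetic-data generator

The generator exists so the pipeline can be tested end to end against a
known truth. Its design:

* **Region**: `nTracts` Voronoi cells of seeded uniform random sites,
  clipped to the extent rectangle by half-plane intersection. Voronoi
  cells guarantee an exact partition (cell areas sum to the extent area to
  1e-6 relative tolerance, a test invariant) and produce the wide spread
  of tract sizes real layers show. Tracts get `XXXX.00`-style names,
  11-digit GEOID-style ids and uniform populations. All geometry lives in
  one planar CRS, 1 unit = 1 m; no geodesy.
* **Latent fields**: K fields of seeded white noise blurred with a
  Gaussian kernel of $\sigma$ = `fieldLengthScale`/`pixelSize` pixels
  (circular boundary), standardized to mean 0, variance 1 over the extent.
  Blurred noise was chosen over an explicit covariance kernel because it
  is cheap at raster scale and gives direct smoothness control.
* **Rasters**: each band is a fixed affine mixture of the K fields plus
  seeded per-pixel noise, affinely rescaled per band into raw integers
  [0, `rawMax`]. The first band's mixing weights are proportional to
  `beta`, so the outcome-relevant latent combination lies inside the
  3-band span of the imagery: with K > 3 a generic 3 × K mixture would
  project out roughly half of the signal and no imagery-based regressor —
  however good — could recover it; aligning one band with `beta`
  guarantees the imagery actually carries the signal whose recovery the
  tests measure. The other two bands are seeded distractor mixtures.
* **Outcomes**: $y_t = \beta_0 + \sum_k \beta_k \bar z_{tk} +
  \varepsilon_t$, with $\bar z_{tk}$ the mean of field k over tract t's
  pixels, $\varepsilon_t \sim N(0, \sigma_\varepsilon^2)$ seeded, rates
  clipped to [0, 100]. The ground truth records the realized signal and
  noise variances and their ratio `trueR2` — the explainable-variance
  fraction an ideal regressor could attain. `calibrateNoiseSd()` sets
  $\sigma_\varepsilon$ from the realized signal variance to hit a target
  `trueR2`; across seeds the realized values concentrate within ±0.05 of
  the target (a test invariant).

Default configuration (the conditions under which the recovery tests
run), with rationale:

| parameter | default | why |
|---|---|---|
| `nTracts` | 250 | large enough for stable 10-fold CV, small enough for minutes-scale runs |
| `extent` | 11.2 × 11.2 km | 1120 × 1120 px at 10 m; tiles evenly into 224- and 56-px chips |
| `pixelSize` | 10 m | the visual-band resolution of the targeted imagery class |
| `nLatent` (K) | 6 | more latent factors than bands, so recovery is non-trivial |
| `fieldLengthScale` | 800 m | comparable to the ~700 m mean tract diameter, so tract means vary smoothly but substantially |
| `beta` | (4, 3, 2, 2, 1, 1) | unequal loadings; signal sd of a few percentage points |
| `outcomeBase` | 39.2% | the median rate of the motivating tract-level obesity data |
| `noiseSd` | 3.5 pp | puts unexplained tract noise on the scale such data show; usually overridden by calibration |
| `populationRange` | 102–75 569 | the population range of the motivating tract data |
| `pixelNoiseSd` | 0.1 | sensor-style noise at 10% of the unit field sd |
| `rawMax` | 10 000 | the integer reflectance convention the normalizer divides away |

**Chip size in the recovery study.** The end-to-end tests tile the
synthetic raster into 56-px (560 m) chips rather than the 224-px default.
The reason is scale fidelity, not convenience: tract feature vectors are
convex combinations of *chip-level* vectors, so imagery information is
effectively chip-resolution, and recovery requires the chip footprint not
to exceed the scale at which tract means vary. In the motivating real
data, chips (2.24 km) are about half the median tract diameter
(~4.5 km); 560 m chips against ~700 m synthetic tracts reproduce that
ratio. With 224-px chips on a 11.2 km extent the chips would be three
tract diameters wide — a regime the real study never operates in.

Problem sizes used by the test suite and acceptance script (the package's
own choices): recovery runs use 250 tracts, K = 6, surrogate D = 256,
forest with 300 trees and default `mtry`, k = 10, swept over 10 seeds,
plus one noiseless run; oracle-equivalence checks use rasters up to
64 × 64 px with up to 5 tracts.

What the generator does **not** emulate — and what passing tests therefore
do not show: real sensor radiometry, clouds and atmospheric effects, UTM
zone overlaps and reprojection, spatially autocorrelated *outcome* error
(survey small-area estimates smooth over space; the generator's
$\varepsilon_t$ is independent), non-linear imagery–outcome links, and the
information content of actual pretrained-CNN activations. A recovery
result on synthetic data validates the plumbing and the estimators, not
the real-world predictive claim.

## 8. Degenerate inputs and numerical edges

* Voronoi generation refuses more tracts than the extent has pixels;
  latent-field generation refuses an extent smaller than one blur length.
* `mergeOutcomes` errors on zero total weight and on any missing member
  rate; `tractFeature`/`chipOutcome` error on zero pixel mass.
* Metrics error on zero variance in the actual values; adjusted R² is NA
  (with a message) when its denominator would be non-positive.
* Boundary-tie pixel assignment is deterministic (smallest id); all
  randomness flows from explicit seeds through an RNG-state-preserving
  wrapper, so library calls never perturb user RNG state.
* Rendered raster values are integers; the 16-bit TIFF round trip is
  exact. World-file georeferencing stores pixel-centre coordinates; the
  reader reconstructs the corner-based affine.

## 9. Known limitations

* Joined geometries being multi-part collections, a hypothetical input
  with *overlapping* subdivision polygons would double-count area; the
  package targets administrative layers where subdivisions partition the
  parent tract.
* The usable-chip filter's coverage test assumes polygonal boundaries
  (exact for them); curved boundary approximations inherit the polygon's
  resolution.
* `selectProducts` treats footprints as identical only when their WKT
  strings match; near-identical footprints from reprocessed products
  should be normalized upstream or handled via the exclusion list.
* Minimum-norm linear fits are reported faithfully even where they
  generalize badly (D ≫ n, ridge = 0); that is a property of the
  estimator, and the ridge argument is the remedy.
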