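---
title: "Measuring built-environment features from street-level imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring built-environment features from street-level imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetscape)
```

## The measurement problem

Many features of a neighbourhood that matter for children's outdoor play —
street trees, sidewalks, pedestrian and vehicle traffic, traffic lights and
signs — are recorded only in scattered municipal datasets, if at all.
Street-level imagery offers a near-universal alternative: photographs taken
along the road network can be segmented pixel-by-pixel into street-scene
classes, and the per-class pixel fractions, aggregated over a neighbourhood,
serve as proxies for the underlying features. `streetscape` implements that
measurement pipeline end to end:

1. **sample** points at fixed intervals along every street;
2. **fetch** four images per point, facing the cardinal directions;
3. **segment** each image into the 19-class street-scene palette and reduce
   each mask to per-class pixel fractions;
4. **aggregate** image fractions into zone-level feature vectors over
   buffers around zone centroids or intersections;
5. **model** ground-truth targets from those features with cross-validated
   regressions, and evaluate how the models transfer to a second city.

The neural network that produces label masks is deliberately *not* part of
the package. Segmentation is a backend contract — any function mapping an
image to a label matrix of the same size with values 0–18/255 — and the
package ships a synthetic city generator whose rendered summaries stand in
for segmented imagery, so the entire pipeline runs and is tested offline.

## Sampling

Points are placed every 150 m by default. For a segment of length $L$ and
spacing $s$, the package places $n = \max(1, \lfloor L/s \rfloor)$ points at
offsets $(i - \tfrac12) \, L/n$. This *centred* rule was chosen over
start-anchored placement because it makes the short-segment case ($L < s$,
one point at the midpoint) the natural $n = 1$ special case rather than an
exception, and it leaves symmetric half-interval margins at segment ends.
One consequence worth knowing: the end margin is $L/2n$, which approaches a
full spacing (not half of one) for segments just under two intervals long.

A point whose four image requests all fail is excluded. Points with partial
imagery (1–3 of 4 images) are kept, and only the fetched images contribute
downstream — discarding them entirely would be stricter than the exclusion
rule requires.

Hexagonal thinning (`hex_downsample`) covers the points' bounding box with a
flat-top hexagonal grid (the cell width is the distance across the flats)
and keeps per cell the point nearest the cell centroid, ties broken by
smallest `point_id`. The tie rules are not scientifically meaningful; they
exist so that thinning is reproducible.

## Segmentation summaries and class collapsing

Masks use the standard 19-class street-scene palette (road, sidewalk,
building, wall, fence, pole, traffic light, traffic sign, vegetation,
terrain, sky, person, rider, car, truck, bus, train, motorcycle, bicycle),
with 255 for void/unlabelled pixels. `summarize_mask` reduces a mask to
per-class fractions of image area; fractions are used instead of raw pixel
counts so that image resolution is irrelevant and measures are comparable
across image sources. The conservation identity (19 fractions + void = 1) is
enforced to $10^{-9}$.

`collapse_classes` implements the modelling taxonomy: `cyclist = bicycle +
rider` and `vehicle = road + car + truck + motorcycle`. `bus` is carried
through but flagged excluded from modelling (too rare to validate);
`terrain` and `sky` are flagged unused. `pole` is retained because pole
pixels feed the traffic-light and traffic-sign models alongside the sign and
light classes themselves. Per-target feature sets are fixed: trees ←
vegetation; sidewalks ← sidewalk; pedestrians ← person; bicycles ← cyclist;
vehicles ← road, car, truck, person; lights/signs ← pole, traffic light,
traffic sign.

## Zones and aggregation

Zone-level exposure is measured inside a buffer around each zone centroid
(500 m by default) or around each intersection for traffic targets.
"Manhattan-style" buffers are implemented literally as the L1 (taxicab) ball
— a diamond whose vertices sit at distance $r$ along the axes — with two
alternatives exposed: Euclidean discs (the default for intersection buffer
sweeps) and network buffers, the set of street locations within $r$ metres
of shortest-path distance, padded by 25 m into an areal zone. All regions
are closed (boundary points count as inside), a determinism choice.

A zone's feature vector is the *unweighted mean over contributing images*
(not over points), so a point with partial imagery contributes
proportionally less. Duplicate (point, heading) pairs are dropped before
averaging, making aggregation idempotent. Zones with no imagery are flagged
missing and excluded from modelling with a warning.

Sidewalk presence is decided per road segment: a segment is
sidewalk-positive when *any* of its images shows a sidewalk fraction of at
least `tau` (default 0.005 of image area). A binary "detected" rule needs a
threshold once detections are fraction-valued; 0.5 % of image area is small
enough to catch genuine sidewalks at the detection range yet above pixel
noise. The zone-level sidewalk target is metres of positively-labelled road
*clipped to the zone polygon*; clipping (rather than counting whole
intersecting segments) keeps the measure monotone in the buffer radius.

## Models and evaluation

Three model families are supported: ordinary least squares, gradient-boosted
trees (200 trees, learning rate 0.1, depth tuned over {2, 3, 4}), and an RBF
support vector machine (cost tuned over {0.25, 1, 4}). Hyperparameters come
from these fixed small grids, chosen by pooled cross-validated RMSE on the
same folds; only the family names are scientifically meaningful, the grids
are pragmatic defaults.

Evaluation uses fivefold cross-validation, stratified by target quartile,
with the fold split a deterministic function of the mandatory seed. Metrics
are RMSE, MAE, and $R^2$ defined as the squared Pearson correlation between
pooled out-of-fold predictions and observations, set to 0 when predictions
are constant — this keeps $R^2 \in [0, 1]$. Note a consequence used in the
transfer analysis below: squared-correlation $R^2$ is blind to sign and
affine miscalibration; the calibration gap (mean prediction − mean
observation) is reported separately.

Inputs and outputs are standardized. Feature standardization statistics are
estimated on the training city and travel with the fitted model, so the same
model can be applied unchanged elsewhere. Targets are standardized *within*
city by default, because different cities may define the same count
differently (e.g. annualized counts versus rush-hour totals); the
alternative (training-city target stats) is available and the choice is
recorded on the result.

For intersection traffic targets the informative spatial scale is unknown, so
`sweep_buffers` fits every family at 40 radii (50–2000 m in 50 m steps) and
reports both the raw RMSE argmin and a *selected* buffer: the smallest
radius whose best-family RMSE is within one standard error (computed from
per-fold RMSEs) of the global minimum. The 1-SE rule operationalizes the
trade-off between buffer size and accuracy; radii whose buffers capture too
little imagery to fit are reported as `NA` and excluded from selection.

## The synthetic city

`city_config`/`synth_city` generate a complete synthetic study area: a
perturbed grid network (boundary lines rural, every fourth interior line an
arterial), ground truth, and per-image class-fraction summaries. The
generator is a pure function of its config; every stage draws from a
sub-seed derived from the master seed.

Ground truth: trees follow an inhomogeneous Poisson process along streets
with a smooth spatial intensity field; sidewalk presence is Bernoulli by
road class (residential 0.95, arterial 0.70, rural 0.05); intersection
traffic is log-normal, boosted by incident arterials over a smooth field;
signs and lights sit at intersections with class-dependent probabilities.

Rendered summaries encode the links the analysis is meant to recover, plus
the two confounders that matter for real imagery:

* vegetation is a logistic function of the trees within 75 m of the point —
  75 m being the typical distance at which objects remain detectable in
  street imagery — plus noise;
* sidewalk fraction is positive where the segment truly has a sidewalk, and
  a *shoulder-confusion* parameter adds false sidewalk signal on rural
  segments, mimicking paved shoulders being mistaken for sidewalks;
* the car fraction has a driving component (increasing in local traffic) and
  a parked component that concentrates where traffic is low, modulated by a
  parking-supply field; at high parking prevalence the car fraction becomes
  *inversely* related to true traffic, while the road fraction decreases
  with traffic throughout;
* all channels are clipped to [0, 1] and co-normalized with a building/sky
  remainder so conservation holds exactly; masks can be rasterized at 64×64
  with largest-remainder apportionment, reproducing fractions to 1/4096.

A config may carry a `shift` block (higher parked-car prevalence, shoulder
confusion, a rescaled traffic definition); `test_city_config` applies it to
produce a companion test city. Training on the base city and evaluating on
the shifted city reproduces the qualitative cross-city failure: vehicle
models lose most of their predictive utility while time-invariant features
(trees, sidewalks) survive.

Per-image Gaussian noise is available per channel, but note that zone
aggregation averages over enough images that i.i.d. noise barely moves
zone-level metrics. The generator therefore also supports a spatially
*correlated* vegetation noise field (`noise_field_sd`), which is the
realistic form of segmentation error (lighting, vegetation type, urban form
vary smoothly) and the component the population-$R^2$ calibration
(`noise_sd_for_r2`) adjusts: it computes the field SD needed for a target
zone-level $R^2$ from the noise-free zone signal variance and the measured
zone-level attenuation of the unit field.

### Calibration study conditions

The parameter-recovery analysis (in the test suite and the acceptance
script) uses a deliberately clean configuration: a regular 20 × 20 grid of
300 m blocks (no vertex jitter), a tree field with 3 km correlation length
and amplitude 1.2, 400 zones of 1000 m L1 radius with centroids kept a full
zone-radius inside the city. These choices make the zone-aggregated
vegetation link an essentially exact affine function of the zone tree count
(noise-free cross-validated $R^2 > 0.99$), so that the calibrated-noise run
isolates the noise calibration itself. With the vegetation noise field
calibrated to a population $R^2$ of 0.60, the cross-validated linear-model
$R^2$ lands near 0.6 (the tests accept 0.45–0.75, allowing for sampling
noise at 400 zones). Shorter tree-field correlation lengths or jittered
geometry lower the noise-free ceiling to roughly 0.95–0.99: the residual is
the genuine mismatch between "trees visible within 75 m of street points"
and "trees inside the buffer polygon", which real inventories share.

The transfer and buffer-sweep experiments use 16 × 16 grids of 300 m blocks
(4.8 km cities), 500 m intersection buffers for the vehicle model, and a
sweep target built by averaging the noise-free person signal within 500 m of
each intersection — a target whose generative scale is known, so the sweep's
argmin radius can be checked against it. Problem sizes throughout (400
zones, ~290 intersections, ~1100–1700 points per city) were chosen as the
smallest at which the zone-level statistics stabilize.

## What the synthetic tests do and do not show

Passing the synthetic suite demonstrates that the pipeline's mechanics are
correct (sampling arithmetic, buffer geometry, conservation, metric
formulas, seeded reproducibility) and that the statistical machinery
recovers effects it was designed to recover, degrades under the encoded
covariate shifts, and selects buffer scales that match a known generative
scale. It does *not* validate a segmentation model (none is included), nor
the magnitudes of real-city error statistics — real imagery has occlusion,
seasonal and temporal variation, capture-date heterogeneity and
API-dependent image geometry that the generator does not emulate.

## Numerical choices and degenerate inputs

* Boundary membership is closed everywhere; the L1 predicate is evaluated
  exactly, with no epsilon.
* Segment clipping solves the piecewise-linear (diamond) or quadratic
  (disc) boundary crossings analytically; network zones clip by arc-length
  intervals.
* Zero-length network segments are dropped at load with a warning; zero-sd
  variables fail standardization with the variable named; zones without
  imagery are excluded with a warning; segments without imagery get missing
  sidewalk labels.
* Duplicate ground-truth years resolve to the most recent; an exact tie is
  an error naming the id rather than a silent choice.
* All geometry lives in a projected metric CRS. Degree-valued input must be
  reprojected at load (UTM via the standard flattening series, checked
  against geodesic distances in the tests); a local metric frame is
  accepted as-is.
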