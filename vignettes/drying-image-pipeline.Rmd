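---
title: "Monitoring fruit drying from tray images: methods and design notes"
author: "dryscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring fruit drying from tray images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryscan)
```

# The problem

Hot-air drying of fruit slices is monitored for two things at once: how much
water has left the product (the moisture ratio, MR) and how much the product's
appearance has degraded (browning, shrinkage, shape distortion). Both are
usually measured off-line -- by weighing trays and by colorimeters that probe
a single spot. A camera above the tray sees the whole batch at every time
point, so if appearance features extracted from the images track the moisture
loss, the images can serve as a *soft sensor* for MR, and the end-of-drying
images can rank process conditions by how fresh-looking their product remains.

`dryscan` implements that pipeline: HSV-threshold segmentation of the slices,
identity tracking across the half-hourly time-lapse, six appearance features
per (slice, time), two MR regression models, and a PCA/distance ranking of
drying conditions. A synthetic scene generator with exact analytic ground
truth makes the whole chain testable without camera data.

# Image processing

## Colour space and segmentation

Frames are converted from RGB to HSV with hue on the half-degree scale
0--180 and saturation/value on 0--255 (the common 8-bit working scale of
image-processing toolkits). The conversion is the standard hexcone formula:
RGB scaled to [0, 1], hue 0 when max = min, otherwise the sector formula with
precedence R, G, B on ties, wrapped into [0, 360) and halved; S is
(max − min)/max (0 for black); V is the maximum channel. `rgbToHSV()` is
verified against `grDevices::rgb2hsv` and round-trips through the standard
inverse within one 8-bit unit.

A pixel is foreground when all three channels fall inside an inclusive
window. The default window -- H 35--75, S 50--255, V 50--255 -- selects
green, saturated, bright fruit flesh against a dark tray. Widening any
interval can only add foreground pixels (a tested invariant). The window is
configuration, not code: other produce or trays need different thresholds.

## Contours, geometry and the perimeter convention

Foreground components are labelled with 8-connectivity (two slices touching
only corner-to-corner remain one component; two blobs separated by
background remain distinct). Components smaller than `minArea` (default
500 px for camera images, 50 px in the test scenes) are dropped as dust.
For each component we record:

* **area** -- the interior pixel count;
* **centroid** -- the mean of interior pixel coordinates (origin top-left,
  y downward);
* **boundary** -- the closed pixel chain from Moore-neighbour tracing;
* **perimeter** -- the chain's arc length, counting 1 per axis step and
  sqrt(2) per diagonal step.

The perimeter convention matters because compactness divides by its square.
The sqrt(2)-weighted chain length is what mainstream contour tooling
(e.g. OpenCV's `arcLength`) reports, and it makes a 10x10 square measure
exactly 36. It is also a known over-estimator of smooth boundaries: for a
digital circle the chain length exceeds the true circumference by about 5%
asymptotically, so the *pixel-derived* compactness of a disk plateaus near
0.90 instead of 1 (we measure 0.902--0.908 at radii 20--100, stable in
radius). The analytic statement "a circle has compactness 1" holds exactly
when the formula `compactness(area, perimeter) = 4*pi*area/perimeter^2` is
fed analytic geometry, and that is how it is tested and reported. Users
comparing pixel compactness across frames are unaffected (the bias is common
to both sides of any comparison), but absolute pixel compactness should not
be read against the theoretical value 1. An unbiased estimator
(Vossepoel--Smeulders corner-corrected chain length) was considered and
rejected: it breaks the exact unit-step convention (the 10x10 square would
no longer measure 36) for a correction that none of the package's
comparisons need.

## Identity tracking

Slices do not move during drying, so identity across frames is geometric:
contours are sorted by centroid y, split into `nRows` equal rows (3 for the
standard 3x3 tray), each row sorted by centroid x, and IDs 0..N−1 assigned
row-major. Ties on y break by x, then by input order, making the mapping
invariant to the order in which contours are discovered. A fixed row count
from configuration was preferred over adaptive row clustering for
determinism: with a known tray layout the equal-split is exact, and a frame
that cannot fill the layout (a lost or merged slice) is *flagged*, not
guessed at.

## Features and record validation

Each (slice, time) record carries the arithmetic mean H, S, V over the
slice interior, area and perimeter normalised by the same slice's baseline
(first) frame, and compactness from the current frame's raw pixel
quantities. The mean is used for hue because the default window sits far
from the 0/180 angular wrap; the documentation warns that this choice is
invalid for windows crossing the wrap.

Records are then screened by rules that encode "a correctly segmented,
monotonically drying slice": normalised area above 1 + 0.05 (slices cannot
grow), a change of more than 0.30 in normalised area relative to the
slice's last accepted record (segmentation merged with a background
artifact, or a dropout), compactness outside (0, 1.05], or membership in a
frame that failed ID assignment. The thresholds are configurable; 0.05
tolerates rasterisation flicker at the baseline, 0.30 is far above any
physical half-hour change yet far below the step caused by a merge. The
jump rule compares against the last *accepted* record rather than the
immediately preceding one so a single anomalous frame does not invalidate
its well-behaved successor.

# The synthetic scene generator

The generator renders what the camera rig sees: a 3x3 tray of green
elliptical slices on a dark background, photographed half-hourly, shrinking
and browning as they dry. Its purpose is exact ground truth, not realism:
no seeds, core or texture, no lighting gradients, no specular glare. What
passing tests demonstrate is therefore that the *algorithms* are correct on
images whose segmentation is unambiguous -- not that the default thresholds
segment every real tray; on camera data the thresholds and `minArea` must
be tuned to the rig, and the validation rules carry the burden the paper's
own exclusions carried.

One drying condition couples every trend to a single first-order decay
rate `k` per half-hourly step (`MR(t) = exp(-k t)`; the default k = 0.3
reaches the conventional MR = 0.05 endpoint at t = 10, i.e. 300 min):

* hue falls by `browning` (default 6.5) hue units per unit of −log MR --
  browning tracks moisture loss most tightly, mirroring pigment kinetics;
* each semi-axis shrinks by `exp(-shrink * k)` per step (default
  shrink = 0.1, i.e. area ratio = MR^0.2, about 0.55 when fully dried),
  with a per-slice ±15% spread in the exponent -- slices shrink at
  individual rates;
* value darkens and saturation rises analogously (weaker coupling, ±50%
  per-slice spread);
* a per-slice *eccentricity drift* multiplies one semi-axis by
  `exp(e t)` and divides the other by it (|e| ≤ 0.06/step). This leaves
  the analytic area ratio exactly `shrink_rate^(2t)` while letting
  perimeter and compactness evolve irregularly -- the anisotropic
  shrinkage of real fruit -- and makes compactness fall during drying.

Ground-truth perimeter and compactness use the Ramanujan ellipse-perimeter
approximation (relative error below 1e-4 at these aspect ratios), the
generator's documented convention. Initial colour is drawn per slice from
tight ranges (hue 58.5--61.5, i.e. fresh green well inside the window);
under the default condition the painted hue stays inside the segmentation
window for the standard 11-frame run and exits it only under harsher or
longer drying, which is how invalid-record handling is exercised.

All randomness is seeded and restores the caller's RNG state; identical
seeds give bit-identical frames and truth tables.

# The moisture-ratio soft sensor

Moisture quantities follow the standard dry-basis definitions:
`M_t = (W_t - W_d)/W_d` and `MR = M_t/M_0`, with the equilibrium moisture
content neglected as usual for high-moisture produce (the type retains the
term so the full ratio is computable if equilibrium data exist). Wet-basis
fractions convert by `wb/(1 - wb)`.

The **standard synthetic study** (`standardSensorDataset`) pools six trays
dried at k = 0.20 .. 0.45 -- 594 (slice, time) records -- with Gaussian
feature noise of 2% of each column's span, emulating measurement noise.
Because hue and area are, by construction, functions of MR alone (up to
small per-slice jitter) while the other four features carry larger
slice-level variability, the planted signal sits in hue and area, matching
the feature-importance structure the camera study observed.

**PLS**: `fitPLS` is a NIPALS PLS1 with internal standardization of the
predictors and centring of the response; predictions are therefore
invariant to affine rescaling of any predictor column. It is cross-checked
in the tests against `mixOmics::pls` and against OLS (to which PLS must
collapse with all components, or with a single predictor). The component
count is chosen by scanning 1..6 and maximising Q² = 1 − PRESS/SS_tot,
with PRESS pooled over all held-out folds of a seeded 5-fold split and
SS_tot taken about the full-response mean (ties prefer fewer components).
Training-set R² and cross-validated Q² are both reported, as they answer
different questions (fit vs generalisation).

**Random forest**: 20 trees (the study's ensemble size) via the
\pkg{randomForest} engine. Every split considers all six predictors
(`mtry = p`), the regression default of the reference scikit-learn
implementation the study used; remaining settings are the engine defaults,
frozen in the model's `params`. Importance is total impurity decrease,
normalised to sum to 1. With `mtry = p` correlated features do not dilute
each other's importance: greedy splitting concentrates credit on the
cleanest predictors, which is the behaviour the study's hue/area-dominated
importance profile reflects.

**Cross-validation protocol**: folds are drawn over individual (slice,
time) records by default, matching the apparent protocol of the study.
This risks temporal leakage -- adjacent time points of one slice are
nearly identical, so record-level CV is optimistic about generalisation to
unseen slices. A leakage-safe mode (`bySlice = TRUE`, whole slices dealt
into folds) is provided for users who need transferable error estimates;
the default remains record-level for comparability.

# Ranking drying conditions

Fresh slices differ from each other, so end-of-drying features are compared
as *relative change*: per slice, (final − baseline)/baseline for each of
the six features, averaged over the group's valid slices. The fresh
reference is a row of zeros by construction -- fresh fruit is unchanged
relative to itself. Columns are then standardized to mean 0 and unit
population standard deviation across groups, putting hue units and
dimensionless ratios on one scale.

PCA (eigendecomposition of the standardized matrix's covariance) provides
scores, loadings and explained-variance fractions for inspection; the sign
of each component is fixed so its largest-magnitude loading is positive,
making loading plots reproducible. The similarity ranking itself uses the
Euclidean distance of each group to the reference row in the *full*
standardized 6-feature space, not a truncated PC space: at full rank the
rotation is an isometry (so the two agree exactly, a tested invariant),
and truncation would discard variance for no benefit in a 6-dimensional
problem. A `pcSpace` option computes truncated-space distances for
comparison with analyses that ranked in 3-PC space. Smallest distance =
most fresh-like condition.

# Numerical choices and degenerate inputs

* Component extraction stops early in PLS when the residual covariance
  norm falls below 1e-12 (exactly collinear designs); constant predictor
  columns are an error naming the column.
* R² is reported as `NA` with a warning when the observed response is
  constant (SS_tot = 0); forest predictions themselves remain defined.
* A single-pixel component receives the degenerate perimeter 1 so the
  positivity invariant holds; `minArea` excludes such components in
  practice.
* Standardization uses the population (divisor-n) standard deviation, so
  standardizing twice is exactly idempotent.
* `kfoldSplit` deals a seeded shuffle round-robin into folds, so fold
  sizes differ by at most one.
* Rendered pixel values are rounded to integers and clipped to [0, 255];
  the background (24, 24, 28) sits below the value threshold by a 5-sigma
  margin at the default noise level.

# Problem sizes

The test suite and the reproduction script run entirely on generated data:
480x480 px frames (slice radii 38--48 px, comfortably above the 20 px
floor at which rasterisation error stays within the 2% area-recovery
band), 11-frame sequences, and the 594-record sensor study. These sizes
were chosen so every property is exercised at comfortable margins -- e.g.
half-hourly area steps of ~6% against ~0.3% rasterisation jitter -- while
a full suite run stays around a minute.

# Known limitations

* The segmentation is a global threshold: low-contrast slice/tray borders
  that defeated the original rig would defeat it too. The validation rules
  flag, rather than repair, such frames.
* Hue averaging assumes the threshold window avoids the 0/180 wrap.
* Pixel compactness carries the ~10% chain-length bias discussed above;
  comparisons across frames are unaffected.
* The abnormal-record rules are a declared surrogate: the original study
  reports how many records it excluded but not its criteria.
* The generator plants first-order MR kinetics; any monotone curve would
  exercise the same code paths, but reported model metrics are specific to
  these conditions and do not predict camera-data performance.
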