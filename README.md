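# dryscan

Image-based monitoring of fruit slice drying: batch feature extraction from
tray time-lapses, a moisture-ratio soft sensor, and appearance-quality
ranking of drying conditions.

## What it does, for whom

Drying trials photograph a tray of fruit slices every half hour while the
tray is weighed. `dryscan` turns those photographs into numbers:

1. **Extraction** — each frame is converted to HSV, thresholded
   (default window H 35–75, S 50–255, V 50–255 on the 0–180 / 0–255
   working scales) into a fruit mask, split into 8-connected components,
   and the components are identified by their fixed tray position (sorted
   by centroid y into rows, by x within rows, IDs row-major). Every
   (slice, time) record carries six appearance features:

   - mean hue *H*, saturation *S*, value *V* over the slice interior;
   - normalised area `A_t / A_t0` and perimeter `P_t / P_t0`
     (baseline = first frame, so both start at exactly 1);
   - compactness `4π·A_t / P_t²` (1 for a perfect circle, smaller for
     elongated or ragged shapes).

   Records that cannot come from a correctly segmented, monotonically
   drying slice (area growth, frame-to-frame jumps, impossible
   compactness, failed ID assignment) are flagged invalid.

2. **Soft sensor** — the moisture ratio `MR = M_t / M_0` with
   `M_t = (W_t − W_d)/W_d` is regressed on the six features with two
   models: NIPALS PLS1 (component count chosen by cross-validated
   Q² = 1 − PRESS/SS_tot) and a 20-tree random forest, both evaluated by
   seeded 5-fold cross-validation (R², Q², MSE, RMSE, MAE; per-fold and
   pooled).

3. **Quality ranking** — end-of-drying appearance is expressed as relative
   change from each slice's fresh baseline, averaged per condition group,
   standardized, summarised by PCA, and ranked by Euclidean distance to
   the fresh reference in the full standardized feature space: smallest
   distance = most fresh-like condition.

A synthetic drying-scene generator (3×3 trays of green ellipses that
shrink, brown and dry under first-order kinetics `MR(t) = e^{−kt}`, with
exact analytic ground truth) backs the test suite and the reproduction
script, so the package is fully exercisable without camera data.

## Worked example

```r
library(dryscan)

## a synthetic drying run: 9 slices, 11 half-hourly frames
tray  <- makeTray(seed = 1)
scene <- renderSequence(tray, nFrames = 11, groupLabel = "60C4ULT", seed = 1)
feats <- validateRecords(trackSequence(scene$frames, pipelineConfig(minArea = 50)))
head(subset(feats, slice_id == 0,
            select = c(slice_id, time_index, hue, value, area, perimeter, compactness)), 4)
#>    slice_id time_index  hue value  area perimeter compactness
#> 1         0          0 60.9   176 1.000     1.000       0.919
#> 10        0          1 58.9   173 0.945     0.972       0.920
#> 19        0          2 57.0   169 0.893     0.950       0.910
#> 28        0          3 55.0   165 0.844     0.927       0.903
```

Slice 0 starts green (hue 60.9) at unit area and browns/shrinks as it
dries; pixel compactness sits near 0.92 (chain-length perimeters of
rasterized near-circles plateau around 0.9 — see the vignette).

```r
## the moisture-ratio soft sensor on the standard 594-record study
ds <- standardSensorDataset(seed = 1)
selectComponents(ds, seed = 1)$q2
#> [1] 0.784 0.806 0.819 0.824 0.855 0.859       # Q2 peaks at 6 components
crossValidate(ds, "pls", seed = 1)
#> RegressionMetrics (n = 594): R2 = 0.8589, MSE = 0.01274, RMSE = 0.1129, MAE = 0.08983
#>   cross-validated: Q2 = 0.8589 (PRESS = 7.568)
#>   5 folds: mean R2 = 0.8556 (sd 0.0263)
crossValidate(ds, "rf", seed = 1)
#> RegressionMetrics (n = 594): R2 = 0.9871, MSE = 0.001168, RMSE = 0.03417, MAE = 0.02099
#>   cross-validated: Q2 = 0.9871 (PRESS = 0.6937)
#>   5 folds: mean R2 = 0.9866 (sd 0.0053)
```

The forest explains ~99% of held-out MR variance and the linear PLS ~86%:
appearance alone recovers moisture state, and the nonlinear model leads.

```r
## ranking drying conditions by distance to fresh appearance:
## three conditions of increasing severity on the same tray layout
conds <- list(Gentle = dryingCondition(k = 0.2),
              Standard = dryingCondition(k = 0.3),
              Harsh = dryingCondition(k = 0.45))
feats <- do.call(rbind, lapply(names(conds), function(g) {
  tr <- simulateGroundTruth(makeTray(seed = 61, condition = conds[[g]]), 11, g)
  data.frame(group_label = tr$group_label, slice_id = tr$slice_id,
             time_index = tr$time_index, hue = tr$hue,
             saturation = tr$saturation, value = tr$value,
             area = tr$area_ratio, perimeter = tr$perimeter_ratio,
             compactness = tr$compactness, valid = TRUE)
}))
rel <- relativeChange(feats[feats$time_index == 10, ],
                      feats[feats$time_index == 0, ])
distanceRanking(rel)
#>      group distance
#> 1    Fresh     0.00
#> 2   Gentle     3.64
#> 3 Standard     4.78
#> 4    Harsh     6.55
```

Gentler drying (smaller k: less browning, less shrinkage) lands closer to
fresh; distances are dimensionless (standardized space).

A thin CLI over the same functions ships in `inst/scripts/dryscan.R`
(subcommands `extract`, `simulate`, `predict`, `rank`; `--config`,
`--seed` flags; CSV in/out, logs to stderr).

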