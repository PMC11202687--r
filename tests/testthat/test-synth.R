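test_that("tray layout is deterministic, complete and non-overlapping", {
  t1 <- makeTray(seed = 1)
  t2 <- makeTray(seed = 1)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 9)
  d <- as.matrix(dist(t1[, c("cx", "cy")])); diag(d) <- Inf
  expect_gt(min(d), max(t1$a0, t1$b0) * 2)
  expect_false(identical(makeTray(seed = 2), t1))
  # single centred slice
  one <- makeTray(1, 1, seed = 1, imageSize = c(200L, 200L))
  expect_equal(one$cx, 100, tolerance = 0.1)
  expect_equal(one$cy, 100, tolerance = 0.1)
  # an impossible layout errors out
  expect_error(makeTray(seed = 1, semiAxes = c(100, 120)), "overlap")
})

test_that("ground truth follows the closed forms", {
  spec <- data.frame(slice_id = 0L, cx = 50, cy = 50, a0 = 20, b0 = 20,
                     hue0 = 60, sat0 = 180, val0 = 180,
                     shrink_rate = 0.9, hue_drift = 1, sat_drift = 0,
                     val_drift = 0, mr_decay_k = 0.3, ecc_drift = 0)
  tr <- simulateGroundTruth(spec, nFrames = 5)
  expect_equal(tr$area_ratio[tr$time_index == 4], 0.9^8)  # a*b scaling
  expect_equal(tr$perimeter_ratio[tr$time_index == 4], 0.9^4)
  expect_equal(tr$mr, exp(-0.3 * (0:4)))
  expect_equal(tr$hue, 60 - (0:4))
  # circular slice: Ramanujan compactness is 1 up to the approximation error
  expect_equal(tr$compactness, rep(1, 5), tolerance = 1e-6)
})

test_that("ground-truth compactness equals the Ramanujan convention", {
  tray <- makeTray(seed = 9)
  tr <- simulateGroundTruth(tray, nFrames = 6)
  ram <- pi * (3 * (tr$a + tr$b) - sqrt((3 * tr$a + tr$b) * (tr$a + 3 * tr$b)))
  expect_equal(tr$compactness, 4 * pi * (pi * tr$a * tr$b) / ram^2,
               tolerance = 1e-12)
  expect_equal(tr$area_ratio,
               rep(tray$shrink_rate, 6)^(2 * tr$time_index),
               tolerance = 1e-12)
  expect_true(all(tr$mr > 0 & tr$mr <= 1))
})

test_that("rendering is seed-deterministic and freezes without change", {
  tray <- makeTray(seed = 10)
  s1 <- renderSequence(tray, nFrames = 2, seed = 5)
  s2 <- renderSequence(tray, nFrames = 2, seed = 5)
  expect_identical(s1$frames[[1]]@pixels, s2$frames[[1]]@pixels)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(
    s1$frames[[1]]@pixels,
    renderSequence(tray, nFrames = 2, seed = 6)$frames[[1]]@pixels))
  # no drying, no shape drift, no noise: every frame is identical
  still <- makeTray(seed = 10,
                    condition = dryingCondition(k = 0, anisoAmp = 0))
  s3 <- renderSequence(still, nFrames = 3, noiseSd = 0, seed = 1)
  expect_identical(s3$frames[[1]]@pixels, s3$frames[[2]]@pixels)
  expect_identical(s3$frames[[2]]@pixels, s3$frames[[3]]@pixels)
})

test_that("hue stays inside the window until late browning", {
  # under the default condition the painted hue remains in the
  # segmentation window for the standard 11-frame run...
  tr <- simulateGroundTruth(makeTray(seed = 12), nFrames = 11)
  expect_true(all(tr$hue >= 35 & tr$hue <= 75))
  # ...but a harsh condition crosses the lower edge eventually
  harsh <- makeTray(seed = 12, condition = dryingCondition(k = 0.6))
  trH <- simulateGroundTruth(harsh, nFrames = 16)
  expect_true(any(trH$hue < 35))
})

test_that("the regression dataset matches the declared schema", {
  tray <- makeTray(seed = 13)
  tr <- simulateGroundTruth(tray, nFrames = 11)
  ds0 <- makeRegressionDataset(tr, noiseFrac = 0)
  expect_s4_class(ds0, "RegressionDataset")
  expect_equal(length(ds0), 99)  # 9 slices x 11 frames
  expect_identical(colnames(featureMatrix(ds0)),
                   c("hue", "saturation", "value", "area", "perimeter",
                     "compactness"))
  # noiseless features are exactly the analytic truth
  expect_equal(unname(featureMatrix(ds0)[, "area"]), tr$area_ratio)
  expect_equal(unname(featureMatrix(ds0)[, "hue"]), tr$hue)
  expect_equal(response(ds0), tr$mr)
  expect_true(all(response(ds0) > 0 & response(ds0) <= 1))
  # noise is seed-deterministic
  dsA <- makeRegressionDataset(tr, noiseFrac = 0.02, seed = 4)
  dsB <- makeRegressionDataset(tr, noiseFrac = 0.02, seed = 4)
  expect_identical(featureMatrix(dsA), featureMatrix(dsB))
})

test_that("the standard sensor study has the documented size and spread", {
  ds <- standardSensorDataset(seed = 1)
  expect_equal(length(ds), 594)  # 6 conditions x 9 slices x 11 frames
  expect_equal(length(unique(recordMeta(ds)$group_label)), 6)
  expect_true(min(response(ds)) < 0.05)  # harshest condition dries fully
  expect_identical(featureMatrix(standardSensorDataset(seed = 1)),
                   featureMatrix(ds))
})

test_that("scenes write to disk and read back through the manifest", {
  dir <- withr::local_tempdir()
  scene <- renderSequence(makeTray(seed = 14), nFrames = 2, seed = 14)
  mpath <- writeScene(scene, dir)
  expect_true(file.exists(mpath))
  frames <- readFrameManifest(mpath)
  expect_length(frames, 2)
  # PNG is lossless: pixel-identical after the round trip
  expect_equal(frames[[1]]@pixels, scene$frames[[1]]@pixels,
               tolerance = 1e-12)
  expect_equal(frames[[2]]@timeIndex, 1L)
})
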