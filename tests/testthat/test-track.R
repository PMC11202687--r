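cfgTest <- pipelineConfig(minArea = 50)

test_that("a shrinking synthetic sequence is tracked completely", {
  scene <- renderSequence(makeTray(seed = 2L), nFrames = 3, seed = 2L)
  feats <- trackSequence(scene$frames, cfgTest)
  expect_equal(nrow(feats), 27)  # 9 slices x 3 frames
  expect_equal(as.vector(table(feats$time_index)), rep(9L, 3))
  expect_true(all(feats$valid))
  for (sid in 0:8) {
    a <- feats$area[feats$slice_id == sid]
    a <- a[order(feats$time_index[feats$slice_id == sid])]
    expect_true(all(diff(a) < 0), label = "area decreases per slice")
  }
  # baseline frame is exactly 1 by construction
  expect_equal(feats$area[feats$time_index == 0], rep(1, 9))
  expect_equal(feats$perimeter[feats$time_index == 0], rep(1, 9))
})

test_that("a single-frame sequence has unit ratios", {
  scene <- renderSequence(makeTray(seed = 3L), nFrames = 1, seed = 3L)
  feats <- trackSequence(scene$frames, cfgTest)
  expect_equal(feats$area, rep(1, 9))
  expect_equal(feats$perimeter, rep(1, 9))
})

test_that("a frame with a missing slice is flagged, not fatal", {
  scene <- renderSequence(makeTray(seed = 4L), nFrames = 3, seed = 4L)
  # blank out one slice in the middle frame
  fr <- scene$frames[[2]]
  px <- fr@pixels
  px[1:160, 1:160, ] <- 24
  scene$frames[[2]] <- imageFrame(px, fr@timeIndex, fr@groupLabel)
  feats <- trackSequence(scene$frames, cfgTest)
  expect_equal(nrow(feats), 27)
  expect_true(all(!feats$valid[feats$time_index == 1]))
  expect_true(all(is.na(feats$area[feats$time_index == 1])))
  expect_true(all(feats$valid[feats$time_index != 1]))
})

test_that("a failing baseline aborts with a diagnostic", {
  scene <- renderSequence(makeTray(seed = 5L), nFrames = 2, seed = 5L)
  dark <- imageFrame(array(24, dim = c(480, 480, 3)), 0L, "sample")
  expect_error(trackSequence(list(dark, scene$frames[[2]]), cfgTest),
               "baseline")
})

test_that("features are invariant to a constant translation", {
  scene <- renderSequence(makeTray(seed = 6L), nFrames = 2, seed = 6L)
  shift <- function(fr, dy, dx) {
    px <- fr@pixels
    out <- array(24, dim = dim(px))
    h <- dim(px)[1]; w <- dim(px)[2]
    out[(1 + dy):h, (1 + dx):w, ] <- px[1:(h - dy), 1:(w - dx), ]
    imageFrame(out, fr@timeIndex, fr@groupLabel)
  }
  base <- trackSequence(scene$frames, cfgTest)
  moved <- trackSequence(lapply(scene$frames, shift, dy = 13L, dx = 7L),
                         cfgTest)
  for (col in c("hue", "saturation", "value", "area", "perimeter",
                "compactness", "pixel_area", "pixel_perimeter"))
    expect_equal(moved[[col]], base[[col]], tolerance = 1e-12,
                 label = paste("translated", col))
})

test_that("validation flags growth, jumps and bad compactness", {
  rec <- data.frame(group_label = "g", slice_id = 0L, time_index = 0:3,
                    hue = 60, saturation = 150, value = 150,
                    area = c(1, 0.95, 0.9, 0.85),
                    perimeter = 1, compactness = 0.9,
                    pixel_area = 100, pixel_perimeter = 36, valid = TRUE)
  expect_true(all(validateRecords(rec)$valid))  # clean sequence stays valid
  grown <- rec; grown$area[3] <- 1.2
  v <- validateRecords(grown)$valid
  expect_identical(v, c(TRUE, TRUE, FALSE, TRUE))
  jumped <- rec; jumped$area[3] <- 0.45  # drop of 0.5 from frame 2
  v2 <- validateRecords(jumped)$valid
  expect_false(v2[3])
  expect_true(v2[2])
  odd <- rec; odd$compactness[4] <- 1.2
  expect_false(validateRecords(odd)$valid[4])
  # a frame that failed ID assignment stays invalid
  failed <- rec; failed$valid[2] <- FALSE
  expect_false(validateRecords(failed)$valid[2])
})

test_that("a clean rendered sequence validates at 100%", {
  scene <- .scene9x11()
  feats <- validateRecords(trackSequence(scene$frames, cfgTest))
  expect_equal(mean(feats$valid), 1)
})

test_that("feature tables round-trip through CSV", {
  scene <- renderSequence(makeTray(seed = 8L), nFrames = 2, seed = 8L)
  feats <- validateRecords(trackSequence(scene$frames, cfgTest))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(feats, path)
  back <- readFeatureTable(path)
  expect_equal(back$area, feats$area, tolerance = 1e-12)
  expect_identical(back$valid, feats$valid)
  expect_identical(names(back), names(feats))
})
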