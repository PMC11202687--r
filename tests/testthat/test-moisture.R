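test_that("moisture content and ratio follow their defining formulas", {
  expect_equal(moistureContent(5, 1), 4)
  expect_equal(moistureContent(3, 3), 0)
  expect_error(moistureContent(5, 0), "positive")
  expect_error(moistureContent(1, 2), "below")
  # 81% wet basis converts to about 4.263 dry basis
  expect_equal(wetToDryBasis(0.81), 0.81 / 0.19)
  expect_equal(wetToDryBasis(0.81), 4.263, tolerance = 1e-3)
  expect_equal(moistureRatio(4, 4), 1)
  expect_equal(moistureRatio(0, 4), 0)
  expect_error(moistureRatio(1, 0), "M0")
  # the usual drying endpoint flag
  M0 <- wetToDryBasis(0.81)
  expect_equal(moistureRatio(0.05 * M0, M0), 0.05)
})

test_that("k-fold splits are disjoint, exhaustive and deterministic", {
  f <- kfoldSplit(10, k = 5, seed = 1)
  expect_length(f, 5)
  expect_equal(lengths(f), rep(2L, 5))
  expect_setequal(unlist(f), 1:10)
  expect_identical(kfoldSplit(10, k = 5, seed = 1), f)
  expect_false(identical(kfoldSplit(10, k = 5, seed = 2), f))
  expect_error(kfoldSplit(3, k = 5), "at least")
  # uneven n still partitions
  f2 <- kfoldSplit(13, k = 5, seed = 3)
  expect_setequal(unlist(f2), 1:13)
  expect_true(max(lengths(f2)) - min(lengths(f2)) <= 1)
  # group-wise: no group straddles folds
  g <- rep(letters[1:6], each = 4)
  fg <- kfoldSplit(24, k = 3, seed = 1, groups = g)
  expect_setequal(unlist(fg), 1:24)
  for (te in fg)
    expect_length(intersect(unique(g[te]), unique(g[-te])), 0)
})

test_that("regression metrics match hand-computed values", {
  y <- c(0.2, 0.5, 0.9)
  perfect <- evaluateRegression(y, y)
  expect_equal(perfect@r2, 1)
  expect_equal(perfect@mse, 0)
  expect_equal(perfect@mae, 0)
  m <- evaluateRegression(c(0, 1), c(1, 0))
  expect_equal(m@mse, 1)
  expect_equal(m@mae, 1)
  expect_equal(m@rmse, 1)
  expect_equal(m@r2, -3)  # SSres = 2, SStot = 0.5
  set.seed(1)
  r <- evaluateRegression(runif(50), runif(50))
  expect_equal(r@mse, r@rmse^2, tolerance = 1e-12)
  expect_lte(r@mae, r@rmse)
  expect_warning(evaluateRegression(rep(1, 5), runif(5)), "constant")
})

test_that("PLS matches ordinary least squares where they must agree", {
  ds <- standardSensorDataset(seed = 1)
  X <- featureMatrix(ds); y <- response(ds)
  # full-component PLS is OLS
  expect_equal(predict(fitPLS(ds, 6), X),
               unname(predict(stats::lm(y ~ X))), tolerance = 1e-8)
  # single-predictor PLS is simple OLS
  x1 <- X[, "area", drop = FALSE]
  expect_equal(predict(fitPLS(x1, 1, y = y), x1),
               unname(predict(stats::lm(y ~ x1))), tolerance = 1e-8)
  # exactly linear response, uncorrelated standardized predictors:
  # one component already fits perfectly
  set.seed(2)
  Q <- qr.Q(qr(scale(matrix(rnorm(400), 100, 4), scale = FALSE)))
  Q <- sweep(Q, 2, apply(Q, 2, sd), "/")
  colnames(Q) <- paste0("x", 1:4)
  yl <- drop(Q %*% c(1, -2, 0.5, 3)) + 2
  fitl <- fitPLS(Q, 1, y = yl)
  expect_equal(predict(fitl, Q), yl, tolerance = 1e-8)
})

test_that("PLS agrees with an independent reference implementation", {
  suppressMessages(requireNamespace("mixOmics"))
  ds <- standardSensorDataset(seed = 3)
  X <- featureMatrix(ds); y <- response(ds)
  for (nc in c(1, 3, 5)) {
    ref <- mixOmics::pls(X, y, ncomp = nc, mode = "regression", scale = TRUE)
    refPred <- unname(predict(ref, X)$predict[, 1, nc])
    expect_equal(predict(fitPLS(ds, nc), X), refPred, tolerance = 1e-8)
  }
})

test_that("PLS predictions are invariant to affine predictor rescaling", {
  ds <- standardSensorDataset(seed = 4)
  X <- featureMatrix(ds); y <- response(ds)
  base <- predict(fitPLS(ds, 3), X)
  X2 <- X
  X2[, "hue"] <- 40 * X2[, "hue"] - 17
  X2[, "area"] <- -2.5 * X2[, "area"] + 0.1
  expect_equal(predict(fitPLS(X2, 3, y = y), X2), base, tolerance = 1e-8)
})

test_that("constant predictors are rejected by name", {
  ds <- standardSensorDataset(seed = 5)
  X <- featureMatrix(ds)
  X[, "value"] <- 7
  expect_error(fitPLS(X, 2, y = response(ds)), "value")
})

test_that("component selection maximises pooled-PRESS Q2 reproducibly", {
  ds <- standardSensorDataset(seed = 1)
  s1 <- selectComponents(ds, seed = 1)
  s2 <- selectComponents(ds, seed = 1)
  expect_identical(s1, s2)
  expect_length(s1$q2, 6)
  expect_true(s1$bestN %in% 1:6)
  expect_equal(s1$bestN, which.max(s1$q2))
  expect_true(all(diff(s1$r2) > -1e-10))  # training R2 never decreases
  # Q2 definition cross-check at the selected count
  cv <- crossValidate(ds, "pls", seed = 1, nComponents = s1$bestN)
  expect_equal(cv@q2, s1$q2[s1$bestN], tolerance = 1e-10)
  expect_equal(cv@q2, 1 - cv@press / sum((response(ds) -
                                          mean(response(ds)))^2))
})

test_that("the forest is seeded, normalised and finds planted signal", {
  ds <- standardSensorDataset(seed = 1)
  rf1 <- fitRF(ds, seed = 1)
  rf2 <- fitRF(ds, seed = 1)
  X <- featureMatrix(ds)
  expect_identical(predict(rf1, X), predict(rf2, X))
  expect_equal(rf1@params$ntree, 20L)
  imp <- featureImportance(rf1)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  # planted two-feature signal: hue and area soak up the importance
  expect_gte(imp[["hue"]] + imp[["area"]], 0.8)
  # hue-only planted signal: hue dominates
  hueOnly <- makeTray(seed = 6, condition = dryingCondition(
    shrink = 0, satShift = 0, valShift = 0, anisoAmp = 0))
  dh <- makeRegressionDataset(simulateGroundTruth(hueOnly, 11),
                              noiseFrac = 0.02, seed = 6)
  imph <- featureImportance(fitRF(dh, seed = 6))
  expect_identical(names(which.max(imph)), "hue")
  # constant response: constant predictions, R2 undefined with warning
  dcst <- regressionDataset(featureMatrix(ds)[1:50, ], rep(0.5, 50),
                            recordMeta(ds)[1:50, ])
  rfc <- suppressWarnings(fitRF(dcst, seed = 1))
  pc <- predict(rfc, featureMatrix(ds)[1:50, ])
  expect_equal(pc, rep(0.5, 50), tolerance = 1e-12)
  expect_warning(mc <- evaluateRegression(rep(0.5, 50), pc), "constant")
  expect_true(is.na(mc@r2))
})

test_that("cross-validation reports per-fold and pooled metrics", {
  ds <- standardSensorDataset(seed = 2)
  cv <- crossValidate(ds, "rf", seed = 2)
  expect_equal(nrow(cv@folds), 5)
  expect_equal(sum(cv@folds$n), length(ds))
  expect_identical(crossValidate(ds, "rf", seed = 2)@folds, cv@folds)
  expect_false(is.na(cv@q2))
  # slice-wise folds keep each slice on one side of the boundary
  cvs <- crossValidate(ds, "pls", seed = 2, nComponents = 3, bySlice = TRUE)
  expect_equal(nrow(cvs@folds), 5)
  expect_false(anyNA(cvs@predicted))
})
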