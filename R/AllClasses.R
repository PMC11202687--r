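#' @import methods
NULL

#' HSV segmentation thresholds
#'
#' Inclusive per-channel bounds used to classify a pixel as fruit foreground.
#' Hue is on the half-degree scale 0--180; saturation and value are on 0--255.
#' The defaults, H (35--75), S (50--255), V (50--255), select green fruit
#' flesh against a dark tray.
#'
#' @slot hLo,hHi hue bounds, 0--180
#' @slot sLo,sHi saturation bounds, 0--255
#' @slot vLo,vHi value (brightness) bounds, 0--255
#' @export
setClass("HSVThresholds",
  representation(hLo = "numeric", hHi = "numeric",
                 sLo = "numeric", sHi = "numeric",
                 vLo = "numeric", vHi = "numeric"))

setValidity("HSVThresholds", function(object) {
  msg <- character()
  for (ch in c("h", "s", "v")) {
    lo <- slot(object, paste0(ch, "Lo")); hi <- slot(object, paste0(ch, "Hi"))
    if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi))
      msg <- c(msg, sprintf("%s bounds must be single non-missing numbers", ch))
    else if (lo > hi)
      msg <- c(msg, sprintf("%sLo must not exceed %sHi", ch, ch))
  }
  if (length(msg) == 0L) {
    if (object@hLo < 0 || object@hHi > 180)
      msg <- c(msg, "hue bounds must lie in [0, 180]")
    if (object@sLo < 0 || object@sHi > 255 || object@vLo < 0 || object@vHi > 255)
      msg <- c(msg, "saturation/value bounds must lie in [0, 255]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn HSVThresholds-class Constructor with the default fruit window.
#' @param hLo,hHi,sLo,sHi,vLo,vHi channel bounds (see slots)
#' @return an \code{HSVThresholds} object
#' @examples
#' hsvThresholds()                 # the default green-fruit window
#' hsvThresholds(hLo = 20, hHi = 90)
#' @export
hsvThresholds <- function(hLo = 35, hHi = 75, sLo = 50, sHi = 255,
                          vLo = 50, vHi = 255) {
  new("HSVThresholds", hLo = as.numeric(hLo), hHi = as.numeric(hHi),
      sLo = as.numeric(sLo), sHi = as.numeric(sHi),
      vLo = as.numeric(vLo), vHi = as.numeric(vHi))
}

setMethod("show", "HSVThresholds", function(object) {
  cat(sprintf("HSVThresholds: H [%g, %g]  S [%g, %g]  V [%g, %g]\n",
              object@hLo, object@hHi, object@sLo, object@sHi,
              object@vLo, object@vHi))
})

#' A single tray photograph
#'
#' One RGB frame of a drying time-lapse: a height x width x 3 array of
#' channel values in [0, 255], the half-hourly time index (0 = the
#' pre-drying baseline) and the experimental group label
#' (e.g. \code{"60C4ULT"}: 60 degC, 4 mm slices, ultrasonic pretreatment).
#' Pixel coordinates follow image convention: origin top-left, x rightward
#' (columns), y downward (rows).
#'
#' @slot pixels numeric array, dim = c(height, width, 3), values in [0, 255]
#' @slot timeIndex non-negative integer, half-hourly steps
#' @slot groupLabel character scalar
#' @export
setClass("ImageFrame",
  representation(pixels = "array", timeIndex = "integer",
                 groupLabel = "character"))

setValidity("ImageFrame", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must be at least 1 x 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  if (length(object@timeIndex) != 1L || is.na(object@timeIndex) ||
      object@timeIndex < 0L)
    return("timeIndex must be a single non-negative integer")
  if (length(object@groupLabel) != 1L)
    return("groupLabel must be a single string")
  TRUE
})

#' @describeIn ImageFrame-class Constructor.
#' @param pixels height x width x 3 array of RGB values in [0, 255]
#' @param timeIndex half-hourly time index (0 = baseline)
#' @param groupLabel experimental group label
#' @return an \code{ImageFrame}
#' @export
imageFrame <- function(pixels, timeIndex = 0L, groupLabel = "sample") {
  new("ImageFrame", pixels = pixels, timeIndex = as.integer(timeIndex),
      groupLabel = as.character(groupLabel))
}

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageFrame %d x %d px, t = %d, group '%s'\n",
              d[1], d[2], object@timeIndex, object@groupLabel))
})

#' @describeIn ImageFrame-class Image dimensions as c(height, width).
#' @param x an \code{ImageFrame}
#' @export
setMethod("dim", "ImageFrame", function(x) dim(x@pixels)[1:2])

#' A detected slice in one frame
#'
#' One connected foreground component: its tracked identity (\code{NA} until
#' IDs are assigned), centroid, closed boundary polygon, interior pixel
#' count, boundary arc length (unit axis steps, sqrt(2) diagonal steps) and
#' the linear indices of its interior pixels in the source mask.
#'
#' @slot sliceId integer, \code{NA} when unassigned; unique within a frame
#' @slot centroid numeric c(x, y), mean of interior pixel coordinates
#' @slot boundary n x 2 matrix of (x, y) boundary pixel centres, implicitly
#'   closed (last point adjacent to first)
#' @slot pixelArea interior pixel count (> 0)
#' @slot pixelPerimeter boundary arc length in pixel units (> 0)
#' @slot pixelIndices integer linear indices of interior pixels (column-major
#'   in the height x width mask)
#' @export
setClass("SliceContour",
  representation(sliceId = "integer", centroid = "numeric",
                 boundary = "matrix", pixelArea = "numeric",
                 pixelPerimeter = "numeric", pixelIndices = "integer"))

setValidity("SliceContour", function(object) {
  if (object@pixelArea <= 0) return("pixelArea must be positive")
  if (object@pixelPerimeter <= 0) return("pixelPerimeter must be positive")
  if (length(object@centroid) != 2L) return("centroid must be (x, y)")
  if (ncol(object@boundary) != 2L) return("boundary must be an n x 2 matrix")
  TRUE
})

setMethod("show", "SliceContour", function(object) {
  cat(sprintf(
    "SliceContour id %s: centroid (%.1f, %.1f), area %g px, perimeter %.2f px\n",
    ifelse(is.na(object@sliceId), "<unassigned>", object@sliceId),
    object@centroid[1], object@centroid[2],
    object@pixelArea, object@pixelPerimeter))
})

#' Feature/response dataset for the moisture-ratio soft sensor
#'
#' Rows are (slice, time) observations. \code{X} holds the six appearance
#' features in fixed column order \code{hue, saturation, value, area,
#' perimeter, compactness} (hue 0--180, saturation/value 0--255, the
#' morphology ratios dimensionless in [0, 1]); \code{y} is the moisture
#' ratio in [0, 1]; \code{meta} carries group/slice/time per row.
#'
#' @slot X numeric matrix, n x 6, columns as above
#' @slot y numeric moisture ratio per row
#' @slot meta data.frame with columns group_label, slice_id, time_index
#' @export
setClass("RegressionDataset",
  representation(X = "matrix", y = "numeric", meta = "data.frame"))

.SENSOR_FEATURES <- c("hue", "saturation", "value",
                      "area", "perimeter", "compactness")

setValidity("RegressionDataset", function(object) {
  if (!identical(colnames(object@X), .SENSOR_FEATURES))
    return(sprintf("X columns must be: %s",
                   paste(.SENSOR_FEATURES, collapse = ", ")))
  if (nrow(object@X) != length(object@y))
    return("X and y disagree on the number of rows")
  if (nrow(object@meta) != length(object@y))
    return("meta and y disagree on the number of rows")
  if (anyNA(object@X) || anyNA(object@y))
    return("X and y must be complete (drop invalid records first)")
  if (any(object@y < 0 | object@y > 1 + 1e-9))
    return("moisture ratio must lie in [0, 1]")
  rng <- cbind(lo = c(0, 0, 0, 0, 0, 0), hi = c(180, 255, 255, 1, 1, 1))
  tol <- 0.1  # rasterisation / noise allowance on the nominal ranges
  for (j in seq_len(6L)) {
    v <- object@X[, j]
    if (any(v < rng[j, 1] - tol * (rng[j, 2] - rng[j, 1])) ||
        any(v > rng[j, 2] + tol * (rng[j, 2] - rng[j, 1])))
      return(sprintf("column '%s' outside its nominal range [%g, %g]",
                     .SENSOR_FEATURES[j], rng[j, 1], rng[j, 2]))
  }
  TRUE
})

#' @describeIn RegressionDataset-class Constructor.
#' @param X n x 6 feature matrix (columns hue, saturation, value, area,
#'   perimeter, compactness)
#' @param y moisture ratio per row
#' @param meta optional per-row metadata (group_label, slice_id, time_index)
#' @export
regressionDataset <- function(X, y, meta = NULL) {
  X <- as.matrix(X)
  if (is.null(meta))
    meta <- data.frame(group_label = "sample", slice_id = NA_integer_,
                       time_index = seq_along(y) - 1L)
  new("RegressionDataset", X = X, y = as.numeric(y), meta = meta)
}

setMethod("show", "RegressionDataset", function(object) {
  cat(sprintf(
    "RegressionDataset: %d records, %d groups, MR in [%.3f, %.3f]\n",
    length(object@y), length(unique(object@meta$group_label)),
    min(object@y), max(object@y)))
})

#' @describeIn RegressionDataset-class Number of records.
#' @export
setMethod("length", "RegressionDataset", function(x) length(x@y))

#' Fitted PLS1 moisture-ratio model
#'
#' A NIPALS partial-least-squares regression of moisture ratio on the six
#' appearance features, fitted on internally standardized predictors.
#' Prediction uses the accumulated regression vector on the original scale.
#'
#' @slot nComponents number of latent components retained
#' @slot coefficients regression vector on the original predictor scale
#' @slot intercept scalar intercept on the original scale
#' @slot weights,loadings,yLoadings NIPALS W, P matrices and q vector
#'   (standardized space), one column/entry per component
#' @slot xCenter,xScale,yCenter standardization parameters
#' @export
setClass("PLSModel",
  representation(nComponents = "integer", coefficients = "numeric",
                 intercept = "numeric", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 xCenter = "numeric", xScale = "numeric", yCenter = "numeric"))

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s), %d predictors\n",
              object@nComponents, length(object@coefficients)))
})

#' Fitted random-forest moisture-ratio model
#'
#' A bootstrap-aggregated ensemble of 20 regression trees (the study's
#' ensemble size) fitted on the six appearance features. Hyperparameters
#' other than the tree count are the \pkg{randomForest} defaults, frozen in
#' \code{params} for reproducibility.
#'
#' @slot forest the underlying \code{randomForest} fit
#' @slot params named list of the hyperparameters used (ntree, mtry,
#'   nodesize, seed)
#' @export
setClass("RFModel", representation(forest = "ANY", params = "list"))

setMethod("show", "RFModel", function(object) {
  cat(sprintf("RFModel: %d trees, mtry = %d (seed %s)\n",
              object@params$ntree, object@params$mtry,
              as.character(object@params$seed)))
})

#' Principal-component summary of appearance change
#'
#' Scores, loadings and explained-variance fractions of a PCA of the
#' standardized relative-change matrix, plus each group's Euclidean
#' distance to the fresh-fruit reference in the full standardized feature
#' space (rotation-invariant, so identical pre- and post-PCA at full rank).
#'
#' @slot scores groups x components score matrix
#' @slot loadings features x components loading matrix; sign fixed so the
#'   largest-magnitude loading of each component is positive
#' @slot explainedVariance variance fraction per retained component,
#'   non-increasing
#' @slot distances named per-group Euclidean distance to the reference row
#' @slot reference the reference group label
#' @export
setClass("PCAResult",
  representation(scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", distances = "numeric",
                 reference = "character"))

setValidity("PCAResult", function(object) {
  ev <- object@explainedVariance
  if (any(ev < -1e-12 | ev > 1 + 1e-12))
    return("explained-variance fractions must lie in [0, 1]")
  if (is.unsorted(rev(ev), strictly = FALSE))
    return("explained-variance fractions must be non-increasing")
  if (sum(ev) > 1 + 1e-12)
    return("explained-variance fractions must sum to at most 1")
  if (length(object@distances) && any(object@distances < 0))
    return("distances must be non-negative")
  TRUE
})

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d groups, %d component(s) (%.1f%% variance)\n",
              nrow(object@scores), ncol(object@scores),
              100 * sum(object@explainedVariance)))
  if (length(object@distances)) {
    cat("Distance to reference (ascending):\n")
    d <- sort(object@distances)
    for (nm in names(d)) cat(sprintf("  %-14s %.3f\n", nm, d[nm]))
  }
})

#' Regression-quality metrics
#'
#' Goodness-of-fit summaries for observed vs predicted moisture ratio:
#' R2 = 1 - SSres/SStot, MSE, RMSE and MAE, plus (after cross-validation)
#' Q2 = 1 - PRESS/SStot from pooled out-of-fold residuals and the per-fold
#' metric table. R2 is \code{NA} when the observed response is constant.
#'
#' @slot r2,q2,mse,rmse,mae scalar metrics (q2 is NA unless cross-validated)
#' @slot press pooled predictive residual sum of squares (NA if not CV)
#' @slot n number of observations
#' @slot folds per-fold metric data.frame (possibly empty)
#' @slot observed,predicted the vectors the metrics summarize
#' @export
setClass("RegressionMetrics",
  representation(r2 = "numeric", q2 = "numeric", mse = "numeric",
                 rmse = "numeric", mae = "numeric", press = "numeric",
                 n = "integer", folds = "data.frame",
                 observed = "numeric", predicted = "numeric"))

setMethod("show", "RegressionMetrics", function(object) {
  cat(sprintf("RegressionMetrics (n = %d): R2 = %s, MSE = %.4g, RMSE = %.4g, MAE = %.4g\n",
              object@n,
              ifelse(is.na(object@r2), "NA", sprintf("%.4f", object@r2)),
              object@mse, object@rmse, object@mae))
  if (!is.na(object@q2))
    cat(sprintf("  cross-validated: Q2 = %.4f (PRESS = %.4g)\n",
                object@q2, object@press))
  if (nrow(object@folds))
    cat(sprintf("  %d folds: mean R2 = %.4f (sd %.4f)\n", nrow(object@folds),
                mean(object@folds$r2), stats::sd(object@folds$r2)))
})

#' Pipeline configuration
#'
#' All tunable settings of the extraction and modelling pipeline, with
#' defaults reproducing the study protocol: the HSV window H 35--75,
#' S 50--255, V 50--255; a 3-row tray of 9 slices; 5-fold cross-validation;
#' a 20-tree forest; up to 6 PLS components.
#'
#' @slot thresholds an \code{HSVThresholds}
#' @slot nRows tray rows used for ID assignment
#' @slot expectedSlices slices expected per frame
#' @slot minArea smallest component kept, in pixels
#' @slot tolGrow allowed fractional area growth above the baseline
#' @slot jumpTol largest allowed frame-to-frame change in normalised area
#' @slot compactEps discretization allowance above 1 for compactness
#' @slot cvK cross-validation folds
#' @slot cvSeed RNG seed for fold assignment and forest fitting
#' @slot rfTrees trees in the random forest
#' @slot plsMaxComponents largest PLS component count scanned
#' @slot referenceGroup label of the fresh reference group
#' @export
setClass("PipelineConfig",
  representation(thresholds = "HSVThresholds", nRows = "integer",
                 expectedSlices = "integer", minArea = "numeric",
                 tolGrow = "numeric", jumpTol = "numeric",
                 compactEps = "numeric", cvK = "integer", cvSeed = "integer",
                 rfTrees = "integer", plsMaxComponents = "integer",
                 referenceGroup = "character"))

setValidity("PipelineConfig", function(object) {
  if (object@nRows < 1L) return("nRows must be at least 1")
  if (object@expectedSlices < 1L) return("expectedSlices must be at least 1")
  if (object@expectedSlices %% object@nRows != 0L)
    return("expectedSlices must be divisible by nRows")
  if (object@minArea < 0) return("minArea must be non-negative")
  if (object@tolGrow < 0 || object@jumpTol <= 0 || object@compactEps < 0)
    return("validation tolerances must be non-negative (jumpTol positive)")
  if (object@cvK < 2L) return("cvK must be at least 2")
  if (object@rfTrees < 1L) return("rfTrees must be at least 1")
  if (object@plsMaxComponents < 1L || object@plsMaxComponents > 6L)
    return("plsMaxComponents must lie in 1..6")
  TRUE
})

#' @describeIn PipelineConfig-class Constructor with the study defaults.
#' @param thresholds HSV segmentation window
#' @param nRows tray rows
#' @param expectedSlices slices per frame
#' @param minArea smallest kept component (px)
#' @param tolGrow,jumpTol,compactEps record-validation tolerances
#' @param cvK,cvSeed cross-validation folds and seed
#' @param rfTrees random-forest size
#' @param plsMaxComponents largest PLS component count scanned
#' @param referenceGroup fresh reference group label
#' @export
pipelineConfig <- function(thresholds = hsvThresholds(), nRows = 3L,
                           expectedSlices = 9L, minArea = 500,
                           tolGrow = 0.05, jumpTol = 0.30, compactEps = 0.05,
                           cvK = 5L, cvSeed = 1L, rfTrees = 20L,
                           plsMaxComponents = 6L, referenceGroup = "Fresh") {
  new("PipelineConfig", thresholds = thresholds, nRows = as.integer(nRows),
      expectedSlices = as.integer(expectedSlices), minArea = minArea,
      tolGrow = tolGrow, jumpTol = jumpTol, compactEps = compactEps,
      cvK = as.integer(cvK), cvSeed = as.integer(cvSeed),
      rfTrees = as.integer(rfTrees),
      plsMaxComponents = as.integer(plsMaxComponents),
      referenceGroup = as.character(referenceGroup))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n  ")
  show(object@thresholds)
  cat(sprintf("  tray: %d rows, %d slices, minArea %g px\n",
              object@nRows, object@expectedSlices, object@minArea))
  cat(sprintf("  validation: tolGrow %.2f, jumpTol %.2f, compactEps %.2f\n",
              object@tolGrow, object@jumpTol, object@compactEps))
  cat(sprintf("  models: %d-fold CV (seed %d), %d trees, <= %d PLS components\n",
              object@cvK, object@cvSeed, object@rfTrees,
              object@plsMaxComponents))
  cat(sprintf("  reference group: '%s'\n", object@referenceGroup))
})
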