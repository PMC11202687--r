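# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards, so generator calls never perturb user RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Ramanujan's ellipse perimeter approximation (relative error < 1e-4 for
# the mild aspect ratios used here); the generator's analytic convention.
ramanujanPerimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Drying-condition parameters for the synthetic generator
#'
#' One drying condition couples every appearance trend to the moisture
#' kinetics through the per-step decay rate \code{k}: the planted moisture
#' ratio is \code{MR(t) = exp(-k t)} (first-order drying in half-hourly
#' steps; the default k = 0.3 reaches the MR = 0.05 drying endpoint at
#' t = 10, i.e. 300 min). Browning shifts hue down by \code{browning} hue
#' units per unit of -log(MR), shrinkage multiplies each semi-axis by
#' \code{exp(-shrink * k)} per step (area ratio = MR^(2 * shrink)), value
#' darkens and saturation rises analogously. \code{anisoAmp} bounds a
#' slice-specific anisotropic shrinkage drift: each slice's aspect ratio
#' changes by its own factor exp(eccDrift * t) with |eccDrift| <= anisoAmp,
#' which preserves the analytic area exactly while letting perimeter and
#' compactness evolve irregularly, as real fruit shrinkage does.
#'
#' @param k moisture-ratio decay rate per half-hourly step
#' @param browning hue units lost per unit -log(MR)
#' @param shrink semi-axis shrink exponent per unit -log(MR)
#' @param valShift value units lost per unit -log(MR)
#' @param satShift saturation units gained per unit -log(MR)
#' @param anisoAmp largest per-step log aspect-ratio drift per slice
#' @return a named list of condition parameters
#' @examples
#' dryingCondition()            # the standard 60 degC-like condition
#' dryingCondition(k = 0.45)    # a harsher, faster-browning condition
#' @export
dryingCondition <- function(k = 0.3, browning = 6.5, shrink = 0.1,
                            valShift = 10, satShift = 4, anisoAmp = 0.06) {
  stopifnot(k >= 0, browning >= 0, shrink >= 0, anisoAmp >= 0)
  list(k = k, browning = browning, shrink = shrink,
       valShift = valShift, satShift = satShift, anisoAmp = anisoAmp)
}

#' Lay out a synthetic tray of elliptical slices
#'
#' Places \code{nRows * nCols} elliptical slice specifications on a
#' jittered grid, with per-slice variation in size, initial colour and
#' drift rates drawn deterministically from \code{seed}. Fresh slices are
#' green (hue near 60 on the 0--180 scale), saturated and bright, i.e.
#' inside the default segmentation window; under the condition's browning
#' rate hue later drifts toward the lower window edge.
#'
#' @param nRows,nCols tray grid (default the study's 3 x 3 layout)
#' @param seed RNG seed; identical seeds give identical trays
#' @param imageSize c(height, width) of the rendered frames, px
#' @param condition a \code{\link{dryingCondition}}
#' @param semiAxes range of initial semi-axis lengths, px
#' @param hue0,sat0,val0 ranges of initial painted HSV per slice
#' @param centerJitter max absolute grid-centre jitter, px
#' @return a data.frame of slice specs (one row per slice) with the tray
#'   geometry in attributes \code{imageSize} and \code{condition}
#' @examples
#' tray <- makeTray(seed = 1)
#' nrow(tray)   # 9
#' @export
makeTray <- function(nRows = 3L, nCols = 3L, seed = 1L,
                     imageSize = c(480L, 480L),
                     condition = dryingCondition(),
                     semiAxes = c(38, 48), hue0 = c(58.5, 61.5),
                     sat0 = c(165, 185), val0 = c(175, 195),
                     centerJitter = 8) {
  stopifnot(nRows >= 1L, nCols >= 1L)
  n <- nRows * nCols
  withSeed(seed, {
    gy <- (seq_len(nRows) - 0.5) / nRows * imageSize[1]
    gx <- (seq_len(nCols) - 0.5) / nCols * imageSize[2]
    grid <- expand.grid(row = seq_len(nRows), col = seq_len(nCols))
    grid <- grid[order(grid$row, grid$col), ]
    specs <- data.frame(
      slice_id = seq_len(n) - 1L,
      cx = gx[grid$col] + stats::runif(n, -centerJitter, centerJitter),
      cy = gy[grid$row] + stats::runif(n, -centerJitter, centerJitter),
      a0 = stats::runif(n, semiAxes[1], semiAxes[2]),
      b0 = stats::runif(n, semiAxes[1], semiAxes[2]),
      hue0 = stats::runif(n, hue0[1], hue0[2]),
      sat0 = stats::runif(n, sat0[1], sat0[2]),
      val0 = stats::runif(n, val0[1], val0[2]),
      shrink_rate = exp(-condition$shrink * condition$k *
                        stats::runif(n, 0.85, 1.15)),
      hue_drift = condition$browning * condition$k,
      sat_drift = condition$satShift * condition$k *
        stats::runif(n, 0.5, 1.5),
      val_drift = condition$valShift * condition$k *
        stats::runif(n, 0.5, 1.5),
      mr_decay_k = condition$k,
      ecc_drift = stats::runif(n, -condition$anisoAmp,
                               condition$anisoAmp))
  })
  maxAx <- max(specs$a0, specs$b0)
  dmat <- as.matrix(stats::dist(specs[, c("cx", "cy")]))
  diag(dmat) <- Inf
  if (any(dmat < 2 * maxAx))
    stop("overlapping slices: grid too tight for the requested semi-axes")
  attr(specs, "imageSize") <- as.integer(imageSize)
  attr(specs, "condition") <- condition
  specs
}

# Semi-axes of slice `sp` at step t: geometric shrinkage times an
# area-preserving anisotropic drift (a*b depends on t only through the
# shrink rate, keeping the analytic area ratio exact).
sliceAxes <- function(sp, t) {
  f <- exp(sp$ecc_drift * t)
  list(a = sp$a0 * sp$shrink_rate^t * f,
       b = sp$b0 * sp$shrink_rate^t / f)
}

#' Analytic ground truth for a tray over time
#'
#' The exact per-(slice, time) quantities the renderer paints: semi-axes,
#' analytic area ratio \code{shrink_rate^(2t)}, perimeter ratio and
#' compactness under the Ramanujan ellipse-perimeter convention, painted
#' HSV (hue clamped to [0, 180], saturation/value to [0, 255]) and the
#' planted moisture ratio \code{exp(-k t)}.
#'
#' @param specs tray from \code{\link{makeTray}}
#' @param nFrames number of half-hourly frames (t = 0 .. nFrames - 1)
#' @param groupLabel label attached to every row
#' @return a data.frame, one row per (slice, time)
#' @export
simulateGroundTruth <- function(specs, nFrames = 11L, groupLabel = "sample") {
  stopifnot(nFrames >= 1L)
  rows <- lapply(seq_len(nFrames) - 1L, function(t) {
    ax <- sliceAxes(specs, t)
    a0x <- sliceAxes(specs, 0L)
    data.frame(
      group_label = groupLabel,
      slice_id = specs$slice_id,
      time_index = t,
      a = ax$a, b = ax$b,
      area_ratio = specs$shrink_rate^(2 * t),
      perimeter_ratio = ramanujanPerimeter(ax$a, ax$b) /
        ramanujanPerimeter(a0x$a, a0x$b),
      compactness = 4 * pi * (pi * ax$a * ax$b) /
        ramanujanPerimeter(ax$a, ax$b)^2,
      hue = pmin(pmax(specs$hue0 - specs$hue_drift * t, 0), 180),
      saturation = pmin(pmax(specs$sat0 + specs$sat_drift * t, 0), 255),
      value = pmin(pmax(specs$val0 - specs$val_drift * t, 0), 255),
      mr = exp(-specs$mr_decay_k * t))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a synthetic drying time-lapse
#'
#' Paints each frame's slices as filled, axis-aligned ellipses of the
#' current analytic size and colour over a dark background that sits
#' outside the default segmentation window, adds i.i.d. Gaussian pixel
#' noise, and returns the frames together with the exact ground truth.
#' Identical seeds give bit-identical output.
#'
#' @param specs tray from \code{\link{makeTray}}
#' @param nFrames number of half-hourly frames
#' @param groupLabel group label stamped on every frame
#' @param background RGB of the tray background (default dark, value < 50)
#' @param noiseSd standard deviation of the additive pixel noise, RGB units
#' @param seed RNG seed for the noise
#' @return \code{list(frames = <list of ImageFrame>, truth = <data.frame>)}
#' @examples
#' scene <- renderSequence(makeTray(seed = 1), nFrames = 2)
#' length(scene$frames); nrow(scene$truth)
#' @export
renderSequence <- function(specs, nFrames = 11L, groupLabel = "sample",
                           background = c(24, 24, 28), noiseSd = 2,
                           seed = 1L) {
  size <- attr(specs, "imageSize")
  stopifnot(!is.null(size), nFrames >= 1L)
  truth <- simulateGroundTruth(specs, nFrames, groupLabel)
  h <- size[1]; w <- size[2]
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  frames <- withSeed(seed, lapply(seq_len(nFrames) - 1L, function(t) {
    px <- array(rep(background, each = h * w), dim = c(h, w, 3L))
    tt <- truth[truth$time_index == t, ]
    for (i in seq_len(nrow(tt))) {
      sp <- specs[i, ]
      inside <- ((xs - sp$cx) / tt$a[i])^2 + ((ys - sp$cy) / tt$b[i])^2 <= 1
      rgb <- hsvToRGB(c(tt$hue[i], tt$saturation[i], tt$value[i]))
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[inside] <- rgb[ch]
        px[, , ch] <- plane
      }
    }
    if (noiseSd > 0)
      px <- px + array(stats::rnorm(length(px), 0, noiseSd), dim = dim(px))
    px <- round(pmin(pmax(px, 0), 255))
    imageFrame(px, timeIndex = t, groupLabel = groupLabel)
  }))
  list(frames = frames, truth = truth)
}

#' Build a soft-sensor dataset from generator ground truth
#'
#' Assembles the six-feature predictor matrix (painted hue, saturation and
#' value; analytic area and perimeter ratios; analytic compactness) and the
#' planted moisture ratio into a \code{\link{RegressionDataset}},
#' optionally adding Gaussian feature noise with standard deviation
#' \code{noiseFrac} of each column's span (measurement noise the camera
#' pipeline would introduce).
#'
#' @param truth ground truth from \code{\link{simulateGroundTruth}} or
#'   \code{\link{renderSequence}}
#' @param noiseFrac per-column noise sd as a fraction of the column span
#' @param seed RNG seed for the feature noise
#' @return a \code{\link{RegressionDataset}}
#' @export
makeRegressionDataset <- function(truth, noiseFrac = 0.02, seed = 1L) {
  X <- as.matrix(truth[, c("hue", "saturation", "value",
                           "area_ratio", "perimeter_ratio", "compactness")])
  colnames(X) <- .SENSOR_FEATURES
  if (noiseFrac > 0) {
    span <- apply(X, 2, function(v) diff(range(v)))
    X <- withSeed(seed, X + matrix(stats::rnorm(length(X)), nrow(X), 6L) *
                    rep(noiseFrac * span, each = nrow(X)))
    # keep noised ratios inside their physical ranges
    for (j in 4:6) X[, j] <- pmin(pmax(X[, j], 1e-6), 1.02)
    X[, 1] <- pmin(pmax(X[, 1], 0), 180)
    for (j in 2:3) X[, j] <- pmin(pmax(X[, j], 0), 255)
  }
  regressionDataset(X, truth$mr,
                    truth[, c("group_label", "slice_id", "time_index")])
}

#' The standard synthetic soft-sensor study
#'
#' Six 3 x 3 trays dried under conditions of increasing severity (decay
#' rates k from 0.2 to 0.45 per step) for 11 half-hourly frames each --
#' 594 (slice, time) records -- with 2% feature noise. This is the seeded
#' dataset used to exercise the PLS and random-forest moisture-ratio
#' models end to end.
#'
#' @param seed RNG seed controlling tray layout and feature noise
#' @param nGroups number of drying conditions
#' @param nFrames frames per condition
#' @param noiseFrac feature noise fraction (see
#'   \code{\link{makeRegressionDataset}})
#' @return a \code{\link{RegressionDataset}}
#' @examples
#' ds <- standardSensorDataset(seed = 1)
#' length(ds)
#' @export
standardSensorDataset <- function(seed = 1L, nGroups = 6L, nFrames = 11L,
                                  noiseFrac = 0.02) {
  ks <- seq(0.2, 0.45, length.out = nGroups)
  truth <- do.call(rbind, lapply(seq_len(nGroups), function(g) {
    tray <- makeTray(seed = seed * 101L + g,
                     condition = dryingCondition(k = ks[g]))
    simulateGroundTruth(tray, nFrames,
                        groupLabel = sprintf("K%03.0f", 100 * ks[g]))
  }))
  makeRegressionDataset(truth, noiseFrac = noiseFrac, seed = seed)
}

#' Write a rendered scene to disk
#'
#' Saves each frame as PNG plus a frame manifest CSV (columns \code{path,
#' time_index, group_label}) and the ground-truth CSV, the layout
#' \code{\link{readFrameManifest}} reads back.
#'
#' @param scene output of \code{\link{renderSequence}}
#' @param dir output directory (created if missing)
#' @return the manifest path, invisibly
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(scene$frames, function(fr) {
    p <- file.path(dir, sprintf("frame_%03d.png", fr@timeIndex))
    png::writePNG(fr@pixels / 255, p)
    p
  }, character(1))
  manifest <- data.frame(
    path = basename(paths),
    time_index = vapply(scene$frames, function(f) f@timeIndex, integer(1)),
    group_label = vapply(scene$frames, function(f) f@groupLabel,
                         character(1)))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(mpath)
}
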