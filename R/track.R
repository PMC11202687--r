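.FEATURE_COLS <- c("group_label", "slice_id", "time_index",
                   "hue", "saturation", "value",
                   "area", "perimeter", "compactness",
                   "pixel_area", "pixel_perimeter", "valid")

#' Track slices through a drying time-lapse and extract features
#'
#' Runs the full per-frame chain -- HSV conversion, threshold segmentation,
#' contour extraction, grid ID assignment -- over a temporally ordered
#' sequence of tray frames, then derives the six appearance features per
#' (slice, time): mean hue/saturation/value over the slice interior, and
#' area/perimeter normalised by the same slice's baseline frame, plus
#' compactness from the current frame's raw pixel quantities.
#'
#' The first frame (smallest time index) is the pre-drying baseline. A
#' frame whose contour count does not match the expected tray layout fails
#' ID assignment; its records are emitted with missing features and
#' \code{valid = FALSE}. A failing baseline aborts the sequence, since no
#' normalisation is possible. Run \code{\link{validateRecords}} afterwards
#' to finalise the validity flags.
#'
#' @param frames list of \code{\link{ImageFrame}} objects (any order; they
#'   are sorted by time index)
#' @param config a \code{\link{PipelineConfig}}
#' @return a feature \code{data.frame} with one row per (slice, time):
#'   columns \code{group_label, slice_id, time_index, hue, saturation,
#'   value, area, perimeter, compactness, pixel_area, pixel_perimeter,
#'   valid}
#' @examples
#' tray <- makeTray(seed = 1)
#' scene <- renderSequence(tray, nFrames = 3)
#' feats <- trackSequence(scene$frames, pipelineConfig(minArea = 50))
#' head(feats)
#' @export
trackSequence <- function(frames, config = pipelineConfig()) {
  stopifnot(length(frames) >= 1L)
  validObject(config)
  ord <- order(vapply(frames, function(f) f@timeIndex, integer(1)))
  frames <- frames[ord]
  baselineContours <- NULL
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    validObject(fr)
    hsv <- rgbToHSV(fr)
    mask <- segmentHSV(hsv, config@thresholds)
    contours <- extractContours(mask, minArea = config@minArea)
    assigned <- NULL
    if (length(contours) == config@expectedSlices)
      assigned <- tryCatch(assignIds(contours, config@nRows),
                           dryscan_id_error = function(e) NULL)
    if (is.null(assigned)) {
      if (fi == 1L)
        stop(sprintf(
          paste("baseline frame (t = %d) failed segmentation:",
                "found %d contour(s), expected %d"),
          fr@timeIndex, length(contours), config@expectedSlices))
      rows[[fi]] <- data.frame(
        group_label = fr@groupLabel,
        slice_id = seq_len(config@expectedSlices) - 1L,
        time_index = fr@timeIndex,
        hue = NA_real_, saturation = NA_real_, value = NA_real_,
        area = NA_real_, perimeter = NA_real_, compactness = NA_real_,
        pixel_area = NA_real_, pixel_perimeter = NA_real_,
        valid = FALSE)
      next
    }
    if (fi == 1L) baselineContours <- assigned
    frameRows <- lapply(assigned, function(ct) {
      cf <- colorFeatures(hsv, ct)
      mf <- morphologyFeatures(ct, baselineContours[[ct@sliceId + 1L]])
      data.frame(group_label = fr@groupLabel, slice_id = ct@sliceId,
                 time_index = fr@timeIndex,
                 hue = cf[["hue"]], saturation = cf[["saturation"]],
                 value = cf[["value"]],
                 area = mf[["area"]], perimeter = mf[["perimeter"]],
                 compactness = mf[["compactness"]],
                 pixel_area = ct@pixelArea,
                 pixel_perimeter = ct@pixelPerimeter,
                 valid = TRUE)
    })
    rows[[fi]] <- do.call(rbind, frameRows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Finalise validity flags on a tracked feature table
#'
#' Marks records that cannot come from a correctly segmented, monotonically
#' drying slice as invalid (the surrogate for the study's exclusion of
#' abnormal records): a record is invalid if its frame already failed ID
#' assignment, if its normalised area exceeds \code{1 + tolGrow} (slices
#' cannot grow during drying), if its normalised area differs by more than
#' \code{jumpTol} from the slice's last accepted record (a merge with a
#' background artifact or a dropout; comparing against the last accepted
#' rather than the immediately preceding record keeps one anomalous frame
#' from invalidating its well-behaved successor), or if compactness falls
#' outside \code{(0, 1 + compactEps]} (the epsilon is a discretization
#' allowance for rasterized shapes).
#'
#' @param records feature table from \code{\link{trackSequence}}
#' @param tolGrow allowed fractional growth above baseline area
#' @param jumpTol largest allowed frame-to-frame normalised-area change
#' @param compactEps allowance above 1 for pixel-derived compactness
#' @return the table with the \code{valid} column finalised
#' @export
validateRecords <- function(records, tolGrow = 0.05, jumpTol = 0.30,
                            compactEps = 0.05) {
  stopifnot(all(.FEATURE_COLS %in% names(records)))
  bad <- !records$valid | is.na(records$area)
  bad <- bad | (!is.na(records$area) & records$area > 1 + tolGrow)
  bad <- bad | (!is.na(records$compactness) &
                (records$compactness <= 0 |
                 records$compactness > 1 + compactEps))
  # area jumps relative to the slice's last accepted record, in time order
  for (key in split(seq_len(nrow(records)),
                    list(records$group_label, records$slice_id),
                    drop = TRUE)) {
    key <- key[order(records$time_index[key])]
    lastGood <- NA_real_
    for (i in key) {
      if (bad[i] || is.na(records$area[i])) next
      if (!is.na(lastGood) && abs(records$area[i] - lastGood) > jumpTol) {
        bad[i] <- TRUE
        next
      }
      lastGood <- records$area[i]
    }
  }
  records$valid <- !bad
  records
}

#' Read a frame manifest and load its images
#'
#' A manifest is a CSV with columns \code{path, time_index, group_label}.
#' Relative paths resolve against the manifest's directory. Alternatively a
#' directory can be given: its PNG/JPEG/TIFF files are taken in
#' lexicographic order with time indices 0, 1, ... and the directory name
#' as group label.
#'
#' @param manifest path to a manifest CSV or to a directory of images
#' @return list of \code{\link{ImageFrame}} objects
#' @export
readFrameManifest <- function(manifest) {
  if (dir.exists(manifest)) {
    paths <- sort(list.files(manifest, full.names = TRUE,
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE))
    if (!length(paths)) stop("no images found in directory: ", manifest)
    info <- data.frame(path = paths, time_index = seq_along(paths) - 1L,
                       group_label = basename(normalizePath(manifest)))
  } else {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    info <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("path", "time_index", "group_label")
    if (!all(need %in% names(info)))
      stop("manifest must have columns: ", paste(need, collapse = ", "))
    rel <- !grepl("^(/|[A-Za-z]:)", info$path)
    info$path[rel] <- file.path(dirname(manifest), info$path[rel])
  }
  lapply(seq_len(nrow(info)), function(i) {
    if (!file.exists(info$path[i]))
      stop("image not found: ", info$path[i])
    readImageFrame(info$path[i], info$time_index[i], info$group_label[i])
  })
}

#' Read one image file as an ImageFrame
#'
#' @param path PNG, JPEG or TIFF file
#' @param timeIndex,groupLabel frame metadata
#' @return an \code{\link{ImageFrame}}
#' @export
readImageFrame <- function(path, timeIndex = 0L, groupLabel = "sample") {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L)
    stop("expected a colour image, got a single channel: ", path)
  if (dim(a)[3] > 3L) a <- a[, , 1:3]  # drop alpha
  pixels <- aperm(a, c(2L, 1L, 3L)) * 255  # EBImage stores (x, y, channel)
  imageFrame(pixels, timeIndex, groupLabel)
}

#' Write / read the feature table CSV
#'
#' The on-disk schema is the documented column set of
#' \code{\link{trackSequence}}; \code{readFeatureTable} checks it on the
#' way back in.
#'
#' @param records feature table
#' @param path CSV path
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns the table
#' @export
writeFeatureTable <- function(records, path) {
  stopifnot(all(.FEATURE_COLS %in% names(records)))
  utils::write.csv(records[, .FEATURE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.FEATURE_COLS %in% names(out)))
    stop("not a dryscan feature table: ", path)
  out$valid <- as.logical(out$valid)
  out
}
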