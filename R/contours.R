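# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels that touch only diagonally are merged afterwards with a small
# union-find pass over the (few) label pairs.
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  lab <- t(lab)
  storage.mode(lab) <- "integer"
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]        # \ diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]       # / diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  }
  k <- max(lab)
  parent <- seq_len(k)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(pairs) && nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[r, 1]); rb <- findRoot(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), findRoot, integer(1))
  # relabel 1..K in order of first appearance (column-major scan), so the
  # labelling is deterministic regardless of merge order
  remap <- match(root, unique(root))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Moore-neighbour boundary tracing (8-connectivity, clockwise in image
# coordinates with y downward). Returns the ordered boundary pixels of the
# component containing (startR, startC), as an n x 2 matrix of (row, col).
traceBoundary <- function(inside, startR, startC) {
  offs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)  # W, NW, N, NE, E, SE, S, SW
  nr <- nrow(inside); nc <- ncol(inside)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && inside[r, c]
  pts <- matrix(c(startR, startC), 1, 2)
  cur <- c(startR, startC)
  back <- 1L  # entered from the west (start pixel is topmost-leftmost)
  limit <- 4L * (nr * nc) + 8L
  for (iter in seq_len(limit)) {
    advanced <- FALSE
    for (k in 0:7) {
      idx <- ((back - 1L + k) %% 8L) + 1L
      cand <- cur + offs[idx, ]
      if (fg(cand[1], cand[2])) {
        if (cand[1] == startR && cand[2] == startC && nrow(pts) > 1L)
          return(pts)
        pts <- rbind(pts, cand)
        # next search starts one past the direction back to the previous
        # pixel (which is foreground by construction)
        back <- ((idx + 4L) %% 8L) + 1L
        cur <- cand
        advanced <- TRUE
        break
      }
    }
    if (!advanced) return(pts)  # isolated pixel
  }
  stop("boundary tracing failed to close")
}

# Arc length of a closed boundary pixel chain: 1 per axis step, sqrt(2) per
# diagonal step. A single-pixel component gets the degenerate length 1.
chainLength <- function(pts) {
  if (nrow(pts) < 2L) return(1)
  d <- rbind(diff(pts), pts[1L, ] - pts[nrow(pts), ])
  sum(sqrt(rowSums(d^2)))
}

#' Extract slice contours from a binary mask
#'
#' Finds the 8-connected foreground components of a segmentation mask and
#' summarises each as a \code{\link{SliceContour}}: centroid (mean of
#' interior pixel coordinates), interior pixel count, closed boundary
#' polygon from Moore-neighbour tracing, and boundary arc length counting
#' unit axis steps and sqrt(2) diagonal steps. Components smaller than
#' \code{minArea} (dust, glare speckles) are dropped.
#'
#' @param mask logical height x width matrix from \code{\link{segmentHSV}}
#' @param minArea smallest component kept, in pixels
#' @return a list of \code{SliceContour} objects with unassigned IDs, in
#'   column-major discovery order; empty when nothing passes the filter
#' @examples
#' m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
#' ct <- extractContours(m, minArea = 10)
#' pixelArea(ct[[1]]); pixelPerimeter(ct[[1]])   # 100 and 36
#' @export
extractContours <- function(mask, minArea = 50) {
  lab <- labelComponents(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  out <- list()
  for (i in seq_len(k)) {
    idx <- which(lab == i)
    if (length(idx) < minArea) next
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    # topmost, then leftmost pixel starts the trace
    o <- order(rows, cols)[1L]
    b <- traceBoundary(lab == i, rows[o], cols[o])
    out[[length(out) + 1L]] <- new("SliceContour",
      sliceId = NA_integer_,
      centroid = c(mean(cols), mean(rows)),        # (x, y)
      boundary = cbind(x = b[, 2], y = b[, 1]),
      pixelArea = length(idx),
      pixelPerimeter = chainLength(b),
      pixelIndices = as.integer(idx))
  }
  out
}

#' Assign tray-position IDs to contours
#'
#' Slices keep their tray position throughout drying, so identity across
#' frames follows from geometry alone: contours are sorted by centroid y
#' (top of the image first), split into \code{nRows} equal-sized rows, each
#' row sorted by centroid x, and IDs 0..N-1 assigned row-major. Ties on y
#' break by x, full ties by input order, so the mapping is invariant to the
#' input ordering of the contours.
#'
#' @param contours list of \code{\link{SliceContour}}
#' @param nRows number of tray rows (3 for the standard 3 x 3 tray)
#' @return the same list, reordered by ID, with \code{sliceId} set
#' @examples
#' m <- matrix(FALSE, 30, 30); m[3:8, 3:8] <- TRUE; m[20:25, 20:25] <- TRUE
#' ct <- assignIds(extractContours(m, minArea = 10), nRows = 2)
#' vapply(ct, sliceId, integer(1))
#' @export
assignIds <- function(contours, nRows = 3L) {
  nRows <- as.integer(nRows)
  stopifnot(nRows >= 1L)
  n <- length(contours)
  if (n %% nRows != 0L)
    stop(errorCondition(
      sprintf("segmentation failure: %d contour(s) cannot fill %d equal rows",
              n, nRows),
      class = c("dryscan_id_error", "error")))
  cx <- vapply(contours, function(ct) ct@centroid[1], numeric(1))
  cy <- vapply(contours, function(ct) ct@centroid[2], numeric(1))
  perRow <- n %/% nRows
  byY <- order(cy, cx)                 # ties on y broken by x, then input order
  idOrder <- integer(n)
  for (r in seq_len(nRows)) {
    rowIdx <- byY[((r - 1L) * perRow + 1L):(r * perRow)]
    idOrder[((r - 1L) * perRow + 1L):(r * perRow)] <- rowIdx[order(cx[rowIdx])]
  }
  out <- contours[idOrder]
  for (i in seq_len(n)) out[[i]]@sliceId <- i - 1L
  out
}

#' Mean colour features of a slice
#'
#' Arithmetic mean of hue, saturation and value over the slice's interior
#' pixels. Hue is angular, but the segmentation window (35--75 by default)
#' keeps it far from the 0/180 wrap, so the plain mean is well defined; do
#' not use this with threshold windows crossing the wrap point.
#'
#' @param hsv HSV raster of the frame the contour came from
#' @param contour a \code{\link{SliceContour}}
#' @return named numeric \code{c(hue, saturation, value)}
#' @export
colorFeatures <- function(hsv, contour) {
  idx <- contour@pixelIndices
  if (length(idx) == 0L) stop("contour has an empty interior")
  plane <- dim(hsv)[1] * dim(hsv)[2]
  c(hue = mean(hsv[idx]),
    saturation = mean(hsv[idx + plane]),
    value = mean(hsv[idx + 2L * plane]))
}

#' Shape factor: compactness
#'
#' \code{4 * pi * area / perimeter^2}: 1 for a perfect circle, tending to 0
#' as the shape elongates or roughens. Accepts analytic or pixel-derived
#' area and perimeter.
#'
#' @param area enclosed area
#' @param perimeter boundary length, same length unit
#' @return dimensionless compactness
#' @examples
#' compactness(pi * 5^2, 2 * pi * 5)   # circle: exactly 1
#' compactness(4^2, 4 * 4)             # square: pi/4
#' @export
compactness <- function(area, perimeter) {
  stopifnot(all(area > 0), all(perimeter > 0))
  4 * pi * area / perimeter^2
}

#' Morphology features relative to the pre-drying baseline
#'
#' Normalised area (current over baseline pixel count), normalised
#' perimeter (current over baseline arc length) and compactness of the
#' current contour. The ratios start at exactly 1 at the baseline frame and
#' fall as the slice shrinks; compactness is computed from the current
#' frame's raw pixel quantities.
#'
#' @param contour current \code{\link{SliceContour}}
#' @param baseline the same slice's contour at the baseline frame
#' @return named numeric \code{c(area, perimeter, compactness)}
#' @export
morphologyFeatures <- function(contour, baseline) {
  if (baseline@pixelArea <= 0 || baseline@pixelPerimeter <= 0)
    stop("baseline contour has nonpositive area or perimeter")
  c(area = contour@pixelArea / baseline@pixelArea,
    perimeter = contour@pixelPerimeter / baseline@pixelPerimeter,
    compactness = compactness(contour@pixelArea, contour@pixelPerimeter))
}
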