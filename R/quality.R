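#' Per-group relative appearance change over drying
#'
#' For each slice present in both tables, computes the signed fractional
#' change \code{(final - baseline) / baseline} of each of the six
#' appearance features, then averages over the group's valid slices.
#' Working in relative change removes the slice-to-slice variation of the
#' fresh fruit, so groups are compared by how much drying altered them. A
#' reference row of zeros is appended for the fresh group: fresh fruit is
#' by construction unchanged relative to itself.
#'
#' @param final feature records at the end of drying (feature-table layout,
#'   at least \code{group_label, slice_id, valid} plus the six features)
#' @param baseline matching records of the same slices before drying
#' @param reference label for the appended fresh reference row
#' @return a data.frame: one row per group (plus the reference), columns
#'   \code{group_label, hue, saturation, value, area, perimeter,
#'   compactness, reference}
#' @export
relativeChange <- function(final, baseline, reference = "Fresh") {
  feats <- .SENSOR_FEATURES
  stopifnot(all(c("group_label", "slice_id", feats) %in% names(final)),
            all(c("group_label", "slice_id", feats) %in% names(baseline)))
  if (!"valid" %in% names(final)) final$valid <- TRUE
  final <- final[final$valid & stats::complete.cases(final[, feats]), ]
  rows <- lapply(split(final, final$group_label), function(fg) {
    base <- baseline[baseline$group_label == fg$group_label[1], ]
    m <- match(fg$slice_id, base$slice_id)
    if (anyNA(m))
      stop("final records without matching baseline slices in group ",
           fg$group_label[1])
    rel <- vapply(feats, function(f) {
      b <- base[[f]][m]
      if (any(b == 0))
        stop("zero baseline value for feature '", f, "' in group ",
             fg$group_label[1])
      mean((fg[[f]] - b) / b)
    }, numeric(1))
    cbind(data.frame(group_label = fg$group_label[1]), as.list(rel))
  })
  out <- do.call(rbind, rows)
  ref <- cbind(data.frame(group_label = reference),
               as.list(stats::setNames(rep(0, length(feats)), feats)))
  out <- rbind(out, ref)
  out$reference <- out$group_label == reference
  rownames(out) <- NULL
  out
}

#' Column-standardize a relative-change table
#'
#' Centres each feature column to mean 0 and scales it to unit population
#' standard deviation (divisor n), across all groups including the
#' reference row. Standardization puts hue units and dimensionless ratios
#' on a common scale before PCA and distance computation.
#'
#' @param records relative-change table from \code{\link{relativeChange}},
#'   or a plain numeric matrix
#' @return a numeric matrix with group labels as row names; standardization
#'   parameters in attributes \code{center} and \code{scale}
#' @export
standardizeFeatures <- function(records) {
  if (is.data.frame(records)) {
    m <- as.matrix(records[, .SENSOR_FEATURES])
    rownames(m) <- records$group_label
  } else m <- as.matrix(records)
  if (nrow(m) < 2L) stop("need at least two groups to standardize")
  ctr <- colMeans(m)
  scl <- sqrt(colMeans(sweep(m, 2, ctr)^2))   # population sd
  if (any(scl == 0))
    stop("constant feature column(s): ",
         paste(colnames(m)[scl == 0], collapse = ", "))
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' PCA of the standardized appearance-change matrix
#'
#' Eigendecomposition of the covariance of the (already standardized)
#' matrix, components ordered by decreasing explained variance. The sign of
#' each component is fixed so its largest-magnitude loading is positive,
#' making loading plots reproducible. Distances to the reference group are
#' computed in the full standardized feature space (not the truncated PC
#' space), so they are invariant to the rotation; see
#' \code{\link{distanceRanking}}.
#'
#' @param mat standardized matrix from \code{\link{standardizeFeatures}}
#'   (rows = groups, row names = labels)
#' @param nComponents components to retain (at most the matrix rank)
#' @param reference row name of the reference group (optional; enables
#'   distances)
#' @return a \code{\link{PCAResult}}
#' @export
pcaFit <- function(mat, nComponents = 3L, reference = NULL) {
  stopifnot(nrow(mat) >= 2L)
  pc <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  nComponents <- as.integer(nComponents)
  if (nComponents > rank)
    stop("nComponents (", nComponents, ") exceeds the matrix rank (",
         rank, ")")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(nComponents), drop = FALSE]
  sco <- pc$x[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {       # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  dists <- numeric(0)
  refLabel <- character(0)
  if (!is.null(reference)) {
    if (!reference %in% rownames(mat))
      stop("reference group '", reference, "' not found")
    refRow <- mat[reference, ]
    dists <- sqrt(rowSums(sweep(mat, 2, refRow)^2))
    refLabel <- reference
  }
  new("PCAResult", scores = sco, loadings = rot,
      explainedVariance = evr[seq_len(nComponents)],
      distances = dists, reference = refLabel)
}

#' Rank drying conditions by appearance similarity to fresh fruit
#'
#' Standardizes the relative-change table, measures each group's Euclidean
#' distance to the fresh reference row in the full standardized six-feature
#' space, and sorts ascending: the smallest distance is the condition whose
#' dried product looks most like fresh fruit. Optionally the distance can
#' be taken in a truncated PC space (\code{pcSpace}); at full rank the two
#' are identical because the rotation is an isometry.
#'
#' @param records relative-change table from \code{\link{relativeChange}}
#' @param reference reference group label (must be present)
#' @param pcSpace \code{NULL} for the full feature space (default), or a
#'   number of principal components to truncate to
#' @return a data.frame \code{(group, distance)} in ascending distance
#'   order, reference first at distance 0
#' @export
distanceRanking <- function(records, reference = "Fresh", pcSpace = NULL) {
  m <- standardizeFeatures(records)
  if (!reference %in% rownames(m))
    stop("reference group '", reference, "' not found")
  if (is.null(pcSpace)) {
    refRow <- m[reference, ]
    d <- sqrt(rowSums(sweep(m, 2, refRow)^2))
  } else {
    pc <- pcaFit(m, nComponents = pcSpace)
    sco <- scores(pc)
    refRow <- sco[reference, ]
    d <- sqrt(rowSums(sweep(sco, 2, refRow)^2))
  }
  out <- data.frame(group = names(d), distance = unname(d))
  out <- out[order(out$distance, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
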