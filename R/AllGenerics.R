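#' Accessor generics
#'
#' Small accessor generics used across the package's S4 result classes.
#'
#' @param object an object
#' @param ... passed to methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"),
           useAsDefault = stats::loadings)

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object, ...) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("distances", function(object, ...) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("metricValues", function(object, ...) standardGeneric("metricValues"))

#' @rdname accessors
#' @export
setGeneric("sliceId", function(object, ...) standardGeneric("sliceId"))

#' @rdname accessors
#' @export
setGeneric("centroid", function(object, ...) standardGeneric("centroid"))

#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object, ...) standardGeneric("pixelArea"))

#' @rdname accessors
#' @export
setGeneric("pixelPerimeter",
           function(object, ...) standardGeneric("pixelPerimeter"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object, ...) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("response", function(object, ...) standardGeneric("response"))

#' @rdname accessors
#' @export
setGeneric("recordMeta", function(object, ...) standardGeneric("recordMeta"))

#' @rdname accessors
#' @export
setMethod("sliceId", "SliceContour", function(object, ...) object@sliceId)

#' @rdname accessors
#' @export
setMethod("centroid", "SliceContour", function(object, ...) object@centroid)

#' @rdname accessors
#' @export
setMethod("pixelArea", "SliceContour", function(object, ...) object@pixelArea)

#' @rdname accessors
#' @export
setMethod("pixelPerimeter", "SliceContour",
          function(object, ...) object@pixelPerimeter)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "RegressionDataset", function(object, ...) object@X)

#' @rdname accessors
#' @export
setMethod("response", "RegressionDataset", function(object, ...) object@y)

#' @rdname accessors
#' @export
setMethod("recordMeta", "RegressionDataset", function(object, ...) object@meta)

#' @rdname accessors
#' @export
setMethod("scores", "PCAResult", function(object, ...) object@scores)

#' @rdname accessors
#' @export
setMethod("loadings", "PCAResult", function(x, ...) x@loadings)

#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCAResult",
          function(object, ...) object@explainedVariance)

#' @rdname accessors
#' @export
setMethod("distances", "PCAResult", function(object, ...) object@distances)

#' @rdname accessors
#' @export
setMethod("metricValues", "RegressionMetrics", function(object, ...)
  c(r2 = object@r2, q2 = object@q2, mse = object@mse,
    rmse = object@rmse, mae = object@mae))
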