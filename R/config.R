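#' Read a pipeline configuration from YAML
#'
#' Any subset of the settings may appear in the file; omitted settings keep
#' the study defaults of \code{\link{pipelineConfig}}. Recognised keys:
#' \code{thresholds} (mapping with \code{h_lo, h_hi, s_lo, s_hi, v_lo,
#' v_hi}), \code{n_rows}, \code{expected_slices}, \code{min_area},
#' \code{tol_grow}, \code{jump_tol}, \code{compact_eps}, \code{cv_k},
#' \code{cv_seed}, \code{rf_trees}, \code{pls_max_components},
#' \code{reference_group}. Unknown keys are an error, so typos surface
#' before any computation.
#'
#' @param path YAML file
#' @return a validated \code{\link{PipelineConfig}}
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("thresholds", "n_rows", "expected_slices", "min_area",
             "tol_grow", "jump_tol", "compact_eps", "cv_k", "cv_seed",
             "rf_trees", "pls_max_components", "reference_group")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  thr <- hsvThresholds()
  if (!is.null(raw$thresholds)) {
    tknown <- c("h_lo", "h_hi", "s_lo", "s_hi", "v_lo", "v_hi")
    textra <- setdiff(names(raw$thresholds), tknown)
    if (length(textra))
      stop("unknown threshold key(s): ", paste(textra, collapse = ", "))
    g <- function(key, default)
      if (is.null(raw$thresholds[[key]])) default else raw$thresholds[[key]]
    thr <- hsvThresholds(g("h_lo", 35), g("h_hi", 75), g("s_lo", 50),
                         g("s_hi", 255), g("v_lo", 50), g("v_hi", 255))
  }
  d <- pipelineConfig()
  g <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  cfg <- pipelineConfig(
    thresholds = thr,
    nRows = g("n_rows", d@nRows),
    expectedSlices = g("expected_slices", d@expectedSlices),
    minArea = g("min_area", d@minArea),
    tolGrow = g("tol_grow", d@tolGrow),
    jumpTol = g("jump_tol", d@jumpTol),
    compactEps = g("compact_eps", d@compactEps),
    cvK = g("cv_k", d@cvK),
    cvSeed = g("cv_seed", d@cvSeed),
    rfTrees = g("rf_trees", d@rfTrees),
    plsMaxComponents = g("pls_max_components", d@plsMaxComponents),
    referenceGroup = g("reference_group", d@referenceGroup))
  validObject(cfg)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config a \code{\link{PipelineConfig}}
#' @param path output YAML file
#' @return \code{path}, invisibly
#' @export
writePipelineConfig <- function(config, path) {
  validObject(config)
  yaml::write_yaml(list(
    thresholds = list(h_lo = config@thresholds@hLo,
                      h_hi = config@thresholds@hHi,
                      s_lo = config@thresholds@sLo,
                      s_hi = config@thresholds@sHi,
                      v_lo = config@thresholds@vLo,
                      v_hi = config@thresholds@vHi),
    n_rows = config@nRows, expected_slices = config@expectedSlices,
    min_area = config@minArea, tol_grow = config@tolGrow,
    jump_tol = config@jumpTol, compact_eps = config@compactEps,
    cv_k = config@cvK, cv_seed = config@cvSeed, rf_trees = config@rfTrees,
    pls_max_components = config@plsMaxComponents,
    reference_group = config@referenceGroup), path)
  invisible(path)
}
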