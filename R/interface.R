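.log <- function(fmt, ...) message(sprintf(fmt, ...))

.echoConfig <- function(config) {
  .log("config: HSV H[%g,%g] S[%g,%g] V[%g,%g]; %d rows x %d slices; minArea %g",
       config@thresholds@hLo, config@thresholds@hHi, config@thresholds@sLo,
       config@thresholds@sHi, config@thresholds@vLo, config@thresholds@vHi,
       config@nRows, config@expectedSlices, config@minArea)
}

#' Extract and validate the feature table from a frame manifest
#'
#' Orchestrates \code{\link{readFrameManifest}},
#' \code{\link{trackSequence}} and \code{\link{validateRecords}}, and
#' writes the feature CSV. This is the \code{extract} CLI subcommand.
#'
#' @param manifest manifest CSV or image directory (see
#'   \code{\link{readFrameManifest}})
#' @param out output CSV path
#' @param config a \code{\link{PipelineConfig}}
#' @return the validated feature table, invisibly
#' @export
runExtract <- function(manifest, out, config = pipelineConfig()) {
  validObject(config)
  .echoConfig(config)
  frames <- readFrameManifest(manifest)
  .log("loaded %d frame(s)", length(frames))
  records <- trackSequence(frames, config)
  records <- validateRecords(records, tolGrow = config@tolGrow,
                             jumpTol = config@jumpTol,
                             compactEps = config@compactEps)
  .log("%d records, %d valid (%.1f%%)", nrow(records), sum(records$valid),
       100 * mean(records$valid))
  writeFeatureTable(records, out)
  invisible(records)
}

#' Render a synthetic drying scene to disk
#'
#' Generates a seeded tray, renders the time-lapse and writes frames,
#' manifest and ground truth under \code{outDir}. This is the
#' \code{simulate} CLI subcommand.
#'
#' @param outDir output directory
#' @param seed RNG seed (tray layout and pixel noise)
#' @param nFrames frames to render
#' @param nRows,nCols tray grid
#' @param condition a \code{\link{dryingCondition}}
#' @param groupLabel group label for the scene
#' @return the manifest path, invisibly
#' @export
runSimulate <- function(outDir, seed = 1L, nFrames = 11L, nRows = 3L,
                        nCols = 3L, condition = dryingCondition(),
                        groupLabel = "synthetic") {
  tray <- makeTray(nRows = nRows, nCols = nCols, seed = seed,
                   condition = condition)
  scene <- renderSequence(tray, nFrames = nFrames, groupLabel = groupLabel,
                          seed = seed)
  mpath <- writeScene(scene, outDir)
  .log("wrote %d frame(s) + manifest + ground truth to %s", nFrames, outDir)
  invisible(mpath)
}

#' Cross-validate a moisture-ratio model and write the metric report
#'
#' Fits and cross-validates the chosen soft sensor on a dataset (a feature
#' CSV joined with a weights CSV, or the standard synthetic study when no
#' input is given) and writes two CSVs: per-fold metrics with a mean/sd
#' summary row, and the out-of-fold predicted-vs-actual table. This is the
#' \code{predict} CLI subcommand.
#'
#' @param dataset a \code{\link{RegressionDataset}}, or \code{NULL} for
#'   \code{\link{standardSensorDataset}(seed)}
#' @param model \code{"pls"} or \code{"rf"}
#' @param out output CSV path for the metrics (the predictions go to
#'   \code{<out base>_predictions.csv})
#' @param k folds
#' @param seed seed for folds, forest and the synthetic dataset
#' @param bySlice group folds by slice identity (leakage-safe split)
#' @return the \code{\link{RegressionMetrics}}, invisibly
#' @export
runPredict <- function(dataset = NULL, model = c("rf", "pls"), out,
                       k = 5L, seed = 1L, bySlice = FALSE) {
  model <- match.arg(model)
  if (is.null(dataset)) {
    .log("no dataset given; using the standard synthetic study (seed %d)",
         seed)
    dataset <- standardSensorDataset(seed = seed)
  }
  cv <- crossValidate(dataset, model = model, k = k, seed = seed,
                      bySlice = bySlice)
  tab <- cv@folds
  summary <- data.frame(
    fold = c("mean", "sd"), n = c(mean(tab$n), stats::sd(tab$n)),
    r2 = c(mean(tab$r2), stats::sd(tab$r2)),
    mse = c(mean(tab$mse), stats::sd(tab$mse)),
    rmse = c(mean(tab$rmse), stats::sd(tab$rmse)),
    mae = c(mean(tab$mae), stats::sd(tab$mae)))
  tab$fold <- as.character(tab$fold)
  utils::write.csv(rbind(tab, summary), out, row.names = FALSE)
  predPath <- sub("(\\.[^.]+)?$", "_predictions.csv", out)
  utils::write.csv(
    cbind(dataset@meta, actual = cv@observed, predicted = cv@predicted),
    predPath, row.names = FALSE)
  .log("%s: mean fold R2 %.4f, Q2 %.4f, RMSE %.4f, MAE %.4f", model,
       mean(tab$r2), cv@q2, cv@rmse, cv@mae)
  invisible(cv)
}

#' Rank drying conditions against the fresh reference
#'
#' Builds the relative-change table from a validated feature table (final
#' frame vs baseline frame per group), runs the PCA summary and writes
#' three CSVs: scores, loadings and the ascending distance ranking. This
#' is the \code{rank} CLI subcommand.
#'
#' @param records validated feature table (or path to its CSV)
#' @param outDir directory for \code{scores.csv}, \code{loadings.csv},
#'   \code{ranking.csv}
#' @param reference fresh reference group label
#' @param nComponents PCA components to report
#' @param pcSpace see \code{\link{distanceRanking}}
#' @return the ranking data.frame, invisibly
#' @export
runRank <- function(records, outDir, reference = "Fresh",
                    nComponents = 3L, pcSpace = NULL) {
  if (is.character(records)) records <- readFeatureTable(records)
  rows <- lapply(split(records, records$group_label), function(g) {
    tmax <- max(g$time_index)
    list(final = g[g$time_index == tmax, ],
         baseline = g[g$time_index == min(g$time_index), ])
  })
  final <- do.call(rbind, lapply(rows, `[[`, "final"))
  baseline <- do.call(rbind, lapply(rows, `[[`, "baseline"))
  rel <- relativeChange(final, baseline, reference = reference)
  m <- standardizeFeatures(rel)
  nComponents <- min(nComponents, nrow(m) - 1L, ncol(m))
  pca <- pcaFit(m, nComponents = nComponents, reference = reference)
  ranking <- distanceRanking(rel, reference = reference, pcSpace = pcSpace)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(group = rownames(scores(pca)), scores(pca)),
                   file.path(outDir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(loadings(pca)),
                              loadings(pca)),
                   file.path(outDir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(ranking, file.path(outDir, "ranking.csv"),
                   row.names = FALSE)
  .log("explained variance: %s",
       paste(sprintf("%.1f%%", 100 * explainedVariance(pca)),
             collapse = ", "))
  invisible(ranking)
}
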