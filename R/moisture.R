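#' Dry-basis moisture content
#'
#' \code{(W_t - W_d) / W_d}: grams of water per gram of dry matter, from
#' the current sample weight and the bone-dry weight.
#'
#' @param Wt current sample weight, g
#' @param Wd bone-dry weight, g (positive, not above \code{Wt})
#' @return moisture content, g water / g dry matter
#' @examples
#' moistureContent(5, 1)    # 4 g water per g dry matter
#' @export
moistureContent <- function(Wt, Wd) {
  if (any(Wd <= 0)) stop("dry weight Wd must be positive")
  if (any(Wt < Wd)) stop("current weight Wt cannot fall below dry weight Wd")
  (Wt - Wd) / Wd
}

#' Moisture ratio
#'
#' The dimensionless fraction of removable moisture remaining,
#' \code{M_t / M_0}. The equilibrium moisture content is neglected, as is
#' standard for high-initial-moisture produce; it would enter as
#' \code{(M_t - M_e) / (M_0 - M_e)} if equilibrium data existed.
#'
#' @param Mt current moisture content
#' @param M0 initial moisture content (positive)
#' @param Me equilibrium moisture content (default 0)
#' @return moisture ratio; 1 at the start of drying, towards 0 when dry
#' @examples
#' moistureRatio(4, 4)    # baseline: 1
#' moistureRatio(0.2, 4)  # late drying: 0.05, the usual endpoint
#' @export
moistureRatio <- function(Mt, M0, Me = 0) {
  if (any(M0 - Me <= 0)) stop("initial moisture content M0 must exceed Me")
  (Mt - Me) / (M0 - Me)
}

#' Convert wet-basis moisture fraction to dry-basis content
#'
#' @param wb water mass as a fraction of total mass, in [0, 1)
#' @return dry-basis moisture content wb / (1 - wb)
#' @examples
#' wetToDryBasis(0.81)   # approx 4.263
#' @export
wetToDryBasis <- function(wb) {
  stopifnot(all(wb >= 0), all(wb < 1))
  wb / (1 - wb)
}

#' Deterministic k-fold split
#'
#' Shuffles indices with the given seed and deals them into \code{k}
#' disjoint, exhaustive, near-equal folds. With \code{groups} given (e.g.
#' slice identities), whole groups are dealt into folds instead, so no
#' group straddles the train/test boundary -- the guard against temporal
#' leakage when adjacent time points of one slice are nearly identical.
#'
#' @param n number of records (or a \code{\link{RegressionDataset}})
#' @param k number of folds
#' @param seed RNG seed
#' @param groups optional per-record grouping factor for group-wise folds
#' @return list of \code{k} integer index vectors (test sets)
#' @examples
#' kfoldSplit(10, k = 5, seed = 1)
#' @export
kfoldSplit <- function(n, k = 5L, seed = 1L, groups = NULL) {
  if (is(n, "RegressionDataset")) n <- length(n)
  k <- as.integer(k)
  if (n < k) stop("need at least k = ", k, " records, got ", n)
  withSeed(seed, {
    if (is.null(groups)) {
      idx <- sample.int(n)
      fold <- rep_len(seq_len(k), n)   # near-equal sizes
      unname(split(idx, fold))
    } else {
      stopifnot(length(groups) == n)
      gs <- sample(unique(groups))
      if (length(gs) < k) stop("fewer groups than folds")
      gfold <- rep_len(seq_len(k), length(gs))
      lapply(seq_len(k), function(f)
        which(groups %in% gs[gfold == f]))
    }
  })
}

#' Regression-quality metrics
#'
#' Computes R2 = 1 - SSres/SStot, MSE, RMSE = sqrt(MSE) and MAE for
#' observed vs predicted values. With a constant observed vector, SStot is
#' zero and R2 is reported as \code{NA} with a warning.
#'
#' @param y observed values
#' @param yhat predicted values, same length
#' @return a \code{\link{RegressionMetrics}} object
#' @examples
#' m <- evaluateRegression(c(0, 1), c(1, 0))
#' metricValues(m)   # R2 = -3, MSE = MAE = 1
#' @export
evaluateRegression <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  res <- y - yhat
  ssTot <- sum((y - mean(y))^2)
  mse <- mean(res^2)
  r2 <- if (ssTot == 0) {
    warning("observed response is constant; R2 is undefined")
    NA_real_
  } else 1 - sum(res^2) / ssTot
  new("RegressionMetrics", r2 = r2, q2 = NA_real_, mse = mse,
      rmse = sqrt(mse), mae = mean(abs(res)), press = NA_real_,
      n = length(y), folds = data.frame(),
      observed = as.numeric(y), predicted = as.numeric(yhat))
}

.checkPredictors <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
}

#' Fit a PLS1 moisture-ratio model
#'
#' NIPALS partial least squares with a single response. Predictors are
#' standardized internally (mean 0, sd 1) and the response centred;
#' components are extracted by the usual NIPALS recursion (weight = scaled
#' covariance of residual X with residual y, score, loading, deflation).
#' Predictions therefore depend only on the data, not on any affine
#' rescaling of individual predictor columns.
#'
#' @param dataset a \code{\link{RegressionDataset}}, or a plain matrix with
#'   \code{y} supplied
#' @param nComponents number of latent components, 1 to the predictor count
#' @param y response when \code{dataset} is a matrix
#' @return a \code{\link{PLSModel}}
#' @examples
#' ds <- standardSensorDataset(seed = 1)
#' fit <- fitPLS(ds, nComponents = 2)
#' head(predict(fit, featureMatrix(ds)))
#' @export
fitPLS <- function(dataset, nComponents = 2L, y = NULL) {
  if (is(dataset, "RegressionDataset")) {
    X <- dataset@X; y <- dataset@y
  } else X <- as.matrix(dataset)
  nComponents <- as.integer(nComponents)
  stopifnot(nComponents >= 1L, nComponents <= ncol(X),
            nrow(X) == length(y), nrow(X) > ncol(X))
  .checkPredictors(X)
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd); yc <- mean(y)
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  ys <- y - yc
  p <- ncol(X)
  W <- P <- matrix(0, p, nComponents)
  q <- numeric(nComponents)
  Xr <- Xs; yr <- ys
  for (a in seq_len(nComponents)) {
    w <- drop(crossprod(Xr, yr))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # residual X carries no covariance with y; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      nComponents <- a - 1L
      break
    }
    w <- w / nw
    tsc <- drop(Xr %*% w)
    tt <- sum(tsc^2)
    P[, a] <- drop(crossprod(Xr, tsc)) / tt
    q[a] <- sum(yr * tsc) / tt
    W[, a] <- w
    Xr <- Xr - tcrossprod(tsc, P[, a])
    yr <- yr - q[a] * tsc
  }
  # regression vector in standardized space, then back to the input scale
  bStd <- W %*% solve(crossprod(P, W), q)
  beta <- drop(bStd) / xs
  new("PLSModel", nComponents = nComponents, coefficients = beta,
      intercept = yc - sum(beta * xc), weights = W, loadings = P,
      yLoadings = q, xCenter = xc, xScale = xs, yCenter = yc)
}

#' @describeIn fitPLS Predict moisture ratio for new feature rows.
#' @param object a fitted \code{PLSModel}
#' @param newdata feature matrix with the training column order
#' @param ... ignored
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object@coefficients) + object@intercept
})

#' Choose the PLS component count by cross-validated Q2
#'
#' Scans component counts 1..\code{maxComponents}. For each count the
#' training-set R2 comes from a full-data fit, and Q2 = 1 - PRESS/SStot
#' from k-fold cross-validation with PRESS pooled over all held-out folds
#' (SStot uses the full-response mean). Returns the count with the largest
#' Q2, preferring the smaller count on ties.
#'
#' @param dataset a \code{\link{RegressionDataset}}
#' @param maxComponents largest count scanned (at most the predictor count)
#' @param k folds
#' @param seed fold-assignment seed
#' @param groups optional grouping for group-wise folds (see
#'   \code{\link{kfoldSplit}})
#' @return \code{list(bestN, r2, q2)} with the per-count curves
#' @examples
#' sel <- selectComponents(standardSensorDataset(seed = 1), seed = 1)
#' sel$bestN
#' @export
selectComponents <- function(dataset, maxComponents = 6L, k = 5L,
                             seed = 1L, groups = NULL) {
  stopifnot(is(dataset, "RegressionDataset"))
  maxComponents <- min(as.integer(maxComponents), ncol(dataset@X))
  folds <- kfoldSplit(length(dataset), k = k, seed = seed, groups = groups)
  y <- dataset@y
  ssTot <- sum((y - mean(y))^2)
  r2 <- q2 <- numeric(maxComponents)
  for (nc in seq_len(maxComponents)) {
    full <- fitPLS(dataset, nComponents = nc)
    r2[nc] <- 1 - sum((y - predict(full, dataset@X))^2) / ssTot
    press <- 0
    for (te in folds) {
      fit <- fitPLS(dataset@X[-te, , drop = FALSE], nComponents = nc,
                    y = y[-te])
      press <- press + sum((y[te] -
                            predict(fit, dataset@X[te, , drop = FALSE]))^2)
    }
    q2[nc] <- 1 - press / ssTot
  }
  list(bestN = which.max(q2), r2 = r2, q2 = q2)
}

#' Fit the random-forest moisture-ratio model
#'
#' A bootstrap-aggregated ensemble of regression trees (20 by default, the
#' study's ensemble size) on the six appearance features. Every split
#' considers all predictors (\code{mtry = p}, the convention of the
#' reference ensemble implementation for regression); remaining
#' hyperparameters are the \pkg{randomForest} defaults. All settings are
#' frozen in the model's \code{params} for the record. Deterministic given
#' \code{seed}.
#'
#' @param dataset a \code{\link{RegressionDataset}}
#' @param nTrees ensemble size
#' @param seed RNG seed for the bootstrap and split sampling
#' @return an \code{\link{RFModel}}
#' @examples
#' rf <- fitRF(standardSensorDataset(seed = 1), seed = 1)
#' featureImportance(rf)
#' @export
fitRF <- function(dataset, nTrees = 20L, seed = 1L) {
  stopifnot(is(dataset, "RegressionDataset"), length(dataset) >= 2L)
  mtry <- ncol(dataset@X)
  forest <- withSeed(seed,
    randomForest::randomForest(x = dataset@X, y = dataset@y,
                               ntree = as.integer(nTrees), mtry = mtry,
                               importance = FALSE))
  new("RFModel", forest = forest,
      params = list(ntree = as.integer(nTrees), mtry = mtry,
                    nodesize = 5L, seed = as.integer(seed)))
}

#' @describeIn fitRF Predict moisture ratio for new feature rows.
#' @param object a fitted \code{RFModel}
#' @param newdata feature matrix with the training column order
#' @param ... ignored
#' @export
setMethod("predict", "RFModel", function(object, newdata, ...) {
  unname(stats::predict(object@forest, as.matrix(newdata)))
})

#' Impurity-based feature importance of the forest
#'
#' Total decrease in node impurity (residual sum of squares) attributed to
#' each feature across all trees, normalised to sum to 1.
#'
#' @param model an \code{\link{RFModel}}
#' @return named importances, non-negative, summing to 1
#' @export
featureImportance <- function(model) {
  stopifnot(is(model, "RFModel"))
  imp <- model@forest$importance[, "IncNodePurity"]
  imp / sum(imp)
}

#' Cross-validate a moisture-ratio model
#'
#' Runs k-fold cross-validation of the PLS or random-forest soft sensor:
#' per-fold R2/MSE/RMSE/MAE on the held-out records, their mean and sd,
#' and a pooled Q2 = 1 - PRESS/SStot over all out-of-fold residuals.
#'
#' @param dataset a \code{\link{RegressionDataset}}
#' @param model \code{"pls"} or \code{"rf"}
#' @param k folds
#' @param seed seed for fold assignment (and the forest bootstrap)
#' @param nComponents PLS components (\code{NULL}: chosen by
#'   \code{\link{selectComponents}})
#' @param nTrees forest size
#' @param bySlice split whole slices into folds instead of single records
#' @return a \code{\link{RegressionMetrics}} with per-fold table and Q2
#' @examples
#' cv <- crossValidate(standardSensorDataset(seed = 1), "rf", seed = 1)
#' cv
#' @export
crossValidate <- function(dataset, model = c("pls", "rf"), k = 5L,
                          seed = 1L, nComponents = NULL, nTrees = 20L,
                          bySlice = FALSE) {
  model <- match.arg(model)
  stopifnot(is(dataset, "RegressionDataset"))
  groups <- if (bySlice)
    interaction(dataset@meta$group_label, dataset@meta$slice_id, drop = TRUE)
  if (model == "pls" && is.null(nComponents))
    nComponents <- selectComponents(dataset, k = k, seed = seed,
                                    groups = groups)$bestN
  folds <- kfoldSplit(length(dataset), k = k, seed = seed, groups = groups)
  y <- dataset@y
  yhat <- rep(NA_real_, length(y))
  perFold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    trainX <- dataset@X[-te, , drop = FALSE]
    fit <- if (model == "pls")
      fitPLS(trainX, nComponents = nComponents, y = y[-te])
    else {
      trainDs <- regressionDataset(trainX, y[-te],
                                   dataset@meta[-te, , drop = FALSE])
      fitRF(trainDs, nTrees = nTrees, seed = seed + f)
    }
    yhat[te] <- predict(fit, dataset@X[te, , drop = FALSE])
    m <- evaluateRegression(y[te], yhat[te])
    perFold[[f]] <- data.frame(fold = f, n = length(te), r2 = m@r2,
                               mse = m@mse, rmse = m@rmse, mae = m@mae)
  }
  foldTab <- do.call(rbind, perFold)
  pooled <- evaluateRegression(y, yhat)
  press <- sum((y - yhat)^2)
  new("RegressionMetrics", r2 = pooled@r2,
      q2 = 1 - press / sum((y - mean(y))^2),
      mse = pooled@mse, rmse = pooled@rmse, mae = pooled@mae,
      press = press, n = length(y), folds = foldTab,
      observed = y, predicted = yhat)
}
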