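mkRecords <- function(group, slice, hue, area) {
  data.frame(group_label = group, slice_id = slice,
             hue = hue, saturation = 150, value = 150,
             area = area, perimeter = sqrt(area), compactness = 0.9,
             valid = TRUE)
}

test_that("relative change is signed, per-slice, group-averaged", {
  base <- mkRecords("A", 0:1, hue = c(60, 60), area = c(1, 1))
  # unchanged appearance -> all zeros
  relSame <- relativeChange(base, base)
  a <- relSame[relSame$group_label == "A", ]
  expect_equal(unlist(a[, c("hue", "area", "perimeter")]),
               c(hue = 0, area = 0, perimeter = 0))
  # area halves in every slice -> -0.5
  fin <- mkRecords("A", 0:1, hue = c(60, 60), area = c(0.5, 0.5))
  relHalf <- relativeChange(fin, base)
  expect_equal(relHalf$area[relHalf$group_label == "A"], -0.5)
  # mixed slices average: hue changes -10% and -20% -> -15%
  fin2 <- mkRecords("A", 0:1, hue = c(54, 48), area = c(0.8, 0.6))
  rel2 <- relativeChange(fin2, base)
  expect_equal(rel2$hue[rel2$group_label == "A"], mean(c(-0.1, -0.2)))
  expect_equal(rel2$area[rel2$group_label == "A"], mean(c(-0.2, -0.4)))
  # the reference row is zero by construction and flagged
  ref <- rel2[rel2$reference, ]
  expect_equal(nrow(ref), 1)
  expect_equal(unlist(ref[, c("hue", "saturation", "value", "area",
                              "perimeter", "compactness")]),
               c(hue = 0, saturation = 0, value = 0, area = 0,
                 perimeter = 0, compactness = 0))
  # zero baseline feature is an error
  badBase <- base; badBase$hue <- 0
  expect_error(relativeChange(fin, badBase), "zero baseline")
  # invalid final records are excluded from the mean
  fin3 <- fin2; fin3$valid[2] <- FALSE
  rel3 <- relativeChange(fin3, base)
  expect_equal(rel3$hue[rel3$group_label == "A"], -0.1)
})

test_that("standardization centres and population-scales every column", {
  m <- matrix(c(1, 3, 2, 8), 2, 2,
              dimnames = list(c("g1", "g2"), c("f1", "f2")))
  z <- standardizeFeatures(m)
  expect_equal(unname(z), matrix(c(-1, 1, -1, 1), 2, 2),
               ignore_attr = TRUE)  # symmetric -> +/-1
  set.seed(9)
  m2 <- matrix(rnorm(60), 10, 6,
               dimnames = list(paste0("g", 1:10), letters[1:6]))
  z2 <- standardizeFeatures(m2)
  expect_lt(max(abs(colMeans(z2))), 1e-12)
  expect_equal(unname(sqrt(colMeans(z2^2))), rep(1, 6), tolerance = 1e-12)
  # idempotent
  z3 <- standardizeFeatures(z2)
  expect_equal(unname(z3), unname(z2), tolerance = 1e-12,
               ignore_attr = TRUE)
  m2[, 2] <- 5
  expect_error(standardizeFeatures(m2), "constant")
})

test_that("PCA orders components, fixes signs and reconstructs", {
  # perfectly collinear data: one component carries all variance
  lin <- cbind(a = c(-2, -1, 0, 1, 2), b = 2 * c(-2, -1, 0, 1, 2))
  rownames(lin) <- paste0("g", 1:5)
  pcLin <- pcaFit(standardizeFeatures(lin), nComponents = 1)
  expect_equal(explainedVariance(pcLin)[1], 1, tolerance = 1e-12)
  set.seed(10)
  m <- matrix(rnorm(48), 8, 6,
              dimnames = list(paste0("g", 1:8), letters[1:6]))
  z <- standardizeFeatures(m)
  pc <- pcaFit(z, nComponents = 6)
  expect_equal(sum(explainedVariance(pc)), 1, tolerance = 1e-12)
  expect_true(all(diff(explainedVariance(pc)) <= 1e-12))
  # full-rank reconstruction
  expect_equal(scores(pc) %*% t(loadings(pc)), z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: each component's largest-magnitude loading positive
  for (j in 1:6)
    expect_gt(loadings(pc)[which.max(abs(loadings(pc)[, j])), j], 0)
  expect_error(pcaFit(z, nComponents = 9), "rank")
})

test_that("distances are reference-anchored and rotation-invariant", {
  conds <- list(Mild = dryingCondition(k = 0.2),
                Medium = dryingCondition(k = 0.3),
                Harsh = dryingCondition(k = 0.45))
  rel <- conditionRelChange(conds)
  rk <- distanceRanking(rel)
  expect_equal(rk$distance[rk$group == "Fresh"], 0)
  expect_identical(rk$group[1], "Fresh")
  # planted severity ordering is recovered
  expect_identical(rk$group, c("Fresh", "Mild", "Medium", "Harsh"))
  # full-rank PC-space distances equal full-space distances (isometry;
  # 4 centred rows span at most 3 dimensions)
  full <- distanceRanking(rel, pcSpace = NULL)
  rkPC <- distanceRanking(rel, pcSpace = 3)
  expect_equal(rkPC$distance[match(full$group, rkPC$group)],
               full$distance, tolerance = 1e-10)
})

test_that("raising one drift parameter strictly raises the distance", {
  # one tray layout per comparison, so only the varied parameter differs
  # between groups; everything else contributes identically per group
  bro <- lapply(c(A = 1, B = 2, C = 4), function(mult)
    dryingCondition(k = 0.3, browning = 6.5 * mult))
  rkB <- distanceRanking(conditionRelChange(bro, sameTray = TRUE))
  expect_identical(rkB$group, c("Fresh", "A", "B", "C"))
  # shrinkage rate only
  shr <- lapply(c(A = 0.05, B = 0.1, C = 0.2), function(sv)
    dryingCondition(k = 0.3, shrink = sv, anisoAmp = 0))
  rkS <- distanceRanking(conditionRelChange(shr, sameTray = TRUE))
  expect_identical(rkS$group, c("Fresh", "A", "B", "C"))
})
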