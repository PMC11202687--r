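# Shared fixtures, all generated in code.

# Rasterized disk mask of radius r centred in an (2r + 11)^2 image.
diskMask <- function(r) {
  n <- 2L * r + 11L
  cx <- (n + 1) / 2
  xy <- expand.grid(row = seq_len(n), col = seq_len(n))
  matrix((xy$row - cx)^2 + (xy$col - cx)^2 <= r^2, n, n)
}

# A uniform-colour RGB frame.
flatFrame <- function(rgb, h = 8L, w = 8L, timeIndex = 0L) {
  imageFrame(array(rep(rgb, each = h * w), dim = c(h, w, 3L)), timeIndex)
}

# Feature-table-shaped records straight from generator ground truth
# (analytic features, no rendering), for the quality module.
truthAsFeatures <- function(truth) {
  data.frame(group_label = truth$group_label, slice_id = truth$slice_id,
             time_index = truth$time_index,
             hue = truth$hue, saturation = truth$saturation,
             value = truth$value, area = truth$area_ratio,
             perimeter = truth$perimeter_ratio,
             compactness = truth$compactness, valid = TRUE)
}

# Relative-change table for groups drying under the given conditions.
# With sameTray = TRUE every condition reuses one tray layout, isolating
# the condition parameters as the only between-group difference.
conditionRelChange <- function(conditions, nFrames = 11L, seed = 1L,
                               sameTray = TRUE) {
  tabs <- lapply(seq_along(conditions), function(i) {
    tray <- makeTray(seed = if (sameTray) seed else seed + i,
                     condition = conditions[[i]])
    tr <- truthAsFeatures(simulateGroundTruth(tray, nFrames,
                                              names(conditions)[i]))
    list(final = tr[tr$time_index == max(tr$time_index), ],
         baseline = tr[tr$time_index == 0, ])
  })
  relativeChange(do.call(rbind, lapply(tabs, `[[`, "final")),
                 do.call(rbind, lapply(tabs, `[[`, "baseline")))
}

# One cached standard scene for the slower imaging tests.
.scene9x11 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- renderSequence(makeTray(seed = 11L), nFrames = 11L,
                               seed = 11L)
    cache
  }
})
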