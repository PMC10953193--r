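# Shared fixtures, built in code.

tiny_model_config <- function(variant = "csp_resnext", fpn = TRUE)
  model_config(variant, use_fpn = fpn, base_channels = 4L, cardinality = 4L)

small_phantom <- function(seed = 11L, n_nodules = 2L)
  generate_phantom(phantom_config(volume_shape = c(64L, 80L, 80L),
                                  n_nodules = n_nodules, seed = seed,
                                  diameter_range = c(4, 20)),
                   scan_id = sprintf("fix_%02d", seed))

# Brute-force nearest-anchor oracle: scores every (anchor, gt) pair by
# distance, lexicographic point order, size gap and size, then lets each
# ground truth take its best-ranked free anchor. Independent of the
# package's vectorised implementation.
oracle_assign_nearest <- function(anchors, gts) {
  label <- rep("negative", nrow(anchors))
  taken <- rep(FALSE, nrow(anchors))
  gt_index <- rep(NA_integer_, nrow(anchors))
  for (i in seq_len(nrow(gts))) {
    scored <- data.frame(
      j = seq_len(nrow(anchors)),
      dist = sqrt((anchors$z - gts$z[i])^2 + (anchors$y - gts$y[i])^2 +
                    (anchors$x - gts$x[i])^2),
      sgap = abs(anchors$size - gts$diameter[i]))
    scored <- scored[order(scored$dist, anchors$z, anchors$y, anchors$x,
                           scored$sgap, anchors$size), ]
    for (j in scored$j) {
      if (taken[j]) next
      taken[j] <- TRUE
      label[j] <- "positive"
      gt_index[j] <- i
      break
    }
  }
  list(label = label, gt_index = gt_index)
}

# Voxelised cube-IoU oracle on a fine subgrid (for integer-aligned cubes a
# unit grid is exact).
oracle_iou_voxel <- function(center_a, size_a, center_b, size_b) {
  lo <- floor(pmin(center_a - size_a / 2, center_b - size_b / 2))
  hi <- ceiling(pmax(center_a + size_a / 2, center_b + size_b / 2))
  gr <- expand.grid(z = seq(lo[1] + 0.5, hi[1] - 0.5),
                    y = seq(lo[2] + 0.5, hi[2] - 0.5),
                    x = seq(lo[3] + 0.5, hi[3] - 0.5))
  in_cube <- function(c0, s) gr$z > c0[1] - s / 2 & gr$z < c0[1] + s / 2 &
    gr$y > c0[2] - s / 2 & gr$y < c0[2] + s / 2 &
    gr$x > c0[3] - s / 2 & gr$x < c0[3] + s / 2
  a <- in_cube(center_a, size_a); b <- in_cube(center_b, size_b)
  sum(a & b) / sum(a | b)
}

# Exhaustive FROC oracle: re-runs greedy matching at every distinct
# threshold instead of labelling once.
oracle_froc <- function(dets, gts, n_scans) {
  thresholds <- sort(unique(dets$probability), decreasing = TRUE)
  do.call(rbind, lapply(thresholds, function(t) {
    sub <- dets[dets$probability >= t, , drop = FALSE]
    m <- match_detections(sub, gts)
    data.frame(threshold = t,
               fp_per_scan = sum(m$dets$match == "FP") / n_scans,
               sensitivity = sum(is.finite(m$gt_hit_prob)) / nrow(gts))
  }))
}
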