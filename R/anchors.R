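#' Enumerate anchor boxes over the pyramid feature grids
#'
#' One cubic anchor per (grid cell, size). Anchor points sit at cell
#' centres: `point = grid_index * stride + stride / 2` in input-voxel
#' coordinates (0-based, voxel-centre convention). Ordering is
#' deterministic: level-major, grid cells in z-fastest linear order, then
#' size ascending — the same ordering the flattened head output uses.
#'
#' @param level_shapes list of integer length-3 grid shapes `(z, y, x)`,
#'   one per level.
#' @param strides integer vector of level strides (default 2, 4, 8).
#' @param sizes anchor edge lengths in voxels (default 5, 10, 20).
#' @return Data frame with columns `level`, `z`, `y`, `x` (anchor point)
#'   and `size`.
#' @export
enumerate_anchors <- function(level_shapes, strides = c(2L, 4L, 8L),
                              sizes = c(5, 10, 20)) {
  stopifnot(length(level_shapes) == length(strides))
  out <- lapply(seq_along(level_shapes), function(lv) {
    sdim <- level_shapes[[lv]]; s <- strides[lv]
    # z-fastest cell order, matching R array linearisation
    cells <- expand.grid(z = seq_len(sdim[1]) - 1L, y = seq_len(sdim[2]) - 1L,
                         x = seq_len(sdim[3]) - 1L)
    n <- nrow(cells)
    data.frame(level = lv,
               z = rep(cells$z * s + s / 2, each = length(sizes)),
               y = rep(cells$y * s + s / 2, each = length(sizes)),
               x = rep(cells$x * s + s / 2, each = length(sizes)),
               size = rep(sizes, times = n))
  })
  do.call(rbind, out)
}

#' Intersection over union of two axis-aligned cubes
#'
#' @param center_a,center_b cube centres, length-3 `(z, y, x)`.
#' @param size_a,size_b cube edge lengths (> 0).
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
iou_cube <- function(center_a, size_a, center_b, size_b) {
  lo <- pmax(center_a - size_a / 2, center_b - size_b / 2)
  hi <- pmin(center_a + size_a / 2, center_b + size_b / 2)
  ov <- pmax(hi - lo, 0)
  inter <- prod(ov)
  inter / (size_a^3 + size_b^3 - inter)
}

# vectorised IoU of all anchors against one ground-truth cube
iou_anchors_gt <- function(anchors, gt_center, gt_diam) {
  inter <- rep(1, nrow(anchors))
  for (j in 1:3) {
    ac <- anchors[[c("z", "y", "x")[j]]]
    lo <- pmax(ac - anchors$size / 2, gt_center[j] - gt_diam / 2)
    hi <- pmin(ac + anchors$size / 2, gt_center[j] + gt_diam / 2)
    inter <- inter * pmax(hi - lo, 0)
  }
  inter / (anchors$size^3 + gt_diam^3 - inter)
}

as_gt_df <- function(gts) {
  if (is.null(gts) || (is.data.frame(gts) && nrow(gts) == 0L))
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      diameter = numeric(0)))
  stopifnot(all(c("z", "y", "x", "diameter") %in% names(gts)))
  if (any(gts$diameter <= 0)) stop("ground-truth diameters must be > 0")
  gts
}

#' Assign anchors by fixed-IoU matching
#'
#' An anchor is positive when its best IoU over ground truths reaches
#' `pos_threshold`, negative when below `neg_threshold`, otherwise ignored.
#' A ground truth that captures no positive is given its highest-IoU anchor,
#' so no nodule goes unsupervised. This is the conventional dense-detector
#' rule; it frequently produces several positives per ground truth.
#'
#' @param anchors data frame from [enumerate_anchors()].
#' @param gts data frame with columns `z`, `y`, `x` (voxel centre) and
#'   `diameter` (voxels); may be empty.
#' @param pos_threshold,neg_threshold IoU thresholds,
#'   `pos_threshold >= neg_threshold`.
#' @return An `anchor_assignment`: data frame with `label` (one of
#'   `"positive"`, `"negative"`, `"ignore"`), `gt_index`, and regression
#'   targets `dz`, `dy`, `dx`, `dd` (positives only).
#' @export
assign_iou <- function(anchors, gts, pos_threshold = 0.5, neg_threshold = 0.3) {
  if (pos_threshold < neg_threshold)
    stop("pos_threshold must be >= neg_threshold")
  gts <- as_gt_df(gts)
  n <- nrow(anchors)
  if (nrow(gts) == 0L)
    return(finish_assignment(anchors, rep("negative", n), rep(NA_integer_, n), gts))
  ious <- sapply(seq_len(nrow(gts)), function(i)
    iou_anchors_gt(anchors, c(gts$z[i], gts$y[i], gts$x[i]), gts$diameter[i]))
  ious <- matrix(ious, nrow = n)
  best <- max.col(ious, ties.method = "first")
  best_iou <- ious[cbind(seq_len(n), best)]
  label <- ifelse(best_iou >= pos_threshold, "positive",
                  ifelse(best_iou < neg_threshold, "negative", "ignore"))
  gt_index <- ifelse(label == "positive", best, NA_integer_)
  # force a positive for any unmatched ground truth
  for (i in seq_len(nrow(gts))) {
    if (!any(gt_index == i, na.rm = TRUE)) {
      j <- which.max(ious[, i])
      label[j] <- "positive"; gt_index[j] <- i
    }
  }
  finish_assignment(anchors, label, gt_index, gts)
}

#' Assign anchors by the nearest-anchor rule
#'
#' Each ground truth selects exactly one positive: the anchor whose point is
#' closest (Euclidean) to its centre, ties broken by lexicographic
#' `(z, y, x)` order of the anchor point; among the anchors sharing that
#' point, the one whose size is closest to the nodule diameter, ties going
#' to the smaller size. If two ground truths select the same anchor, the
#' closer one keeps it and the other takes its next-best anchor. All other
#' anchors are negative, except near-misses with IoU above `ignore_iou`
#' against any ground truth, which are ignored and excluded from the loss.
#'
#' @inheritParams assign_iou
#' @param ignore_iou IoU above which a non-positive anchor is ignored.
#' @return An `anchor_assignment` (see [assign_iou()]); exactly one positive
#'   per ground truth.
#' @export
assign_nearest <- function(anchors, gts, ignore_iou = 0.3) {
  gts <- as_gt_df(gts)
  n <- nrow(anchors)
  label <- rep("negative", n)
  gt_index <- rep(NA_integer_, n)
  if (nrow(gts) > 0L) {
    # ignore near-hits first; positives override below
    for (i in seq_len(nrow(gts))) {
      iou <- iou_anchors_gt(anchors, c(gts$z[i], gts$y[i], gts$x[i]),
                            gts$diameter[i])
      label[iou > ignore_iou] <- "ignore"
    }
    # rank anchors per gt: distance, then lexicographic point, then size gap,
    # then smaller size
    for (i in seq_len(nrow(gts))) {
      d2 <- (anchors$z - gts$z[i])^2 + (anchors$y - gts$y[i])^2 +
        (anchors$x - gts$x[i])^2
      ord <- order(d2, anchors$z, anchors$y, anchors$x,
                   abs(anchors$size - gts$diameter[i]), anchors$size)
      for (j in ord) {
        if (label[j] == "positive") next      # taken by an earlier gt
        label[j] <- "positive"; gt_index[j] <- i
        break
      }
    }
  }
  finish_assignment(anchors, label, gt_index, gts)
}

finish_assignment <- function(anchors, label, gt_index, gts) {
  out <- anchors
  out$label <- label
  out$gt_index <- gt_index
  out$dz <- out$dy <- out$dx <- out$dd <- NA_real_
  pos <- which(label == "positive")
  for (j in pos) {
    t <- encode_targets(c(anchors$z[j], anchors$y[j], anchors$x[j]),
                        anchors$size[j],
                        c(gts$z[gt_index[j]], gts$y[gt_index[j]], gts$x[gt_index[j]]),
                        gts$diameter[gt_index[j]])
    out$dz[j] <- t[1]; out$dy[j] <- t[2]; out$dx[j] <- t[3]; out$dd[j] <- t[4]
  }
  class(out) <- c("anchor_assignment", class(out))
  out
}

#' Encode and decode box regression targets
#'
#' Offsets are the ground-truth centre minus the anchor point, divided by
#' the anchor size; the size target is the log ratio of diameter to anchor
#' size. `decode_prediction()` inverts the encoding exactly.
#'
#' @param anchor_point length-3 `(z, y, x)` anchor point.
#' @param anchor_size anchor edge length (> 0).
#' @param gt_center length-3 ground-truth centre.
#' @param gt_diameter ground-truth diameter (> 0).
#' @return `encode_targets()`: numeric `(dz, dy, dx, dd)`.
#' @export
encode_targets <- function(anchor_point, anchor_size, gt_center, gt_diameter) {
  if (gt_diameter <= 0) stop("gt_diameter must be > 0")
  c((gt_center - anchor_point) / anchor_size, log(gt_diameter / anchor_size))
}

#' @rdname encode_targets
#' @param regression numeric `(dz, dy, dx, dd)`.
#' @param probability detection probability in `[0, 1]`.
#' @return `decode_prediction()`: list with `center` `(z, y, x)`, `diameter`
#'   and `probability`.
#' @export
decode_prediction <- function(anchor_point, anchor_size, regression,
                              probability = NA_real_) {
  list(center = anchor_point + regression[1:3] * anchor_size,
       diameter = anchor_size * exp(regression[4]),
       probability = probability)
}
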