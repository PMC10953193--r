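#' Inference configuration
#'
#' @param patch_size sliding-window tile edge, voxels (divisible by 8).
#' @param patch_overlap tile overlap, voxels; at least 20 (the largest
#'   anchor) so no nodule can fall undetectably across a tile boundary.
#' @param probability_floor minimum probability kept before suppression.
#' @param nms_iou cube-IoU above which a lower-probability detection is
#'   suppressed; the low default also merges cross-tile duplicates.
#' @param max_detections_per_scan cap on reported detections.
#' @param pre_nms_topk at most this many highest-probability candidates per
#'   tile (and, pooled, per scan) enter suppression — the usual guard
#'   against floods of low-confidence anchors from weakly calibrated models.
#' @param mask_margin dilation margin (voxels, city-block) applied to the
#'   lung mask before filtering.
#' @return An `inference_config` list.
#' @export
inference_config <- function(patch_size = 64L, patch_overlap = 24L,
                             probability_floor = 0.05, nms_iou = 0.1,
                             max_detections_per_scan = 100L,
                             pre_nms_topk = 1000L,
                             mask_margin = 2L) {
  if (patch_overlap < 20L)
    stop("patch_overlap must be >= 20 voxels (the largest anchor size)")
  if (patch_size %% 8L != 0L) stop("patch_size must be divisible by 8")
  if (patch_overlap >= patch_size) stop("patch_overlap must be < patch_size")
  structure(list(patch_size = as.integer(patch_size),
                 patch_overlap = as.integer(patch_overlap),
                 probability_floor = probability_floor,
                 nms_iou = nms_iou,
                 max_detections_per_scan = as.integer(max_detections_per_scan),
                 pre_nms_topk = as.integer(pre_nms_topk),
                 mask_margin = as.integer(mask_margin)),
            class = "inference_config")
}

tile_origins_1d <- function(extent, patch, stride) {
  if (extent <= patch) return(0L)
  o <- seq(0L, extent - patch, by = stride)
  if (o[length(o)] + patch < extent) o <- c(o, extent - patch)
  o
}

#' Whole-volume detection by sliding-window inference
#'
#' Tiles the normalised volume with the configured overlap (zero-padding
#' volumes smaller than one tile), runs the model on each tile, decodes all
#' anchors above the probability floor, maps them to volume voxel and world
#' coordinates, and resolves cross-tile duplicates by global 3D NMS.
#'
#' @param vol a `normalized_volume` (1 mm isotropic grid).
#' @param model an `rpn3d_model`.
#' @param cfg an [inference_config()].
#' @param lung_mask optional binary mask on the same grid; when supplied,
#'   extrapulmonary detections are removed (see [mask_filter()]).
#' @return Data frame of detections: `seriesuid`, `coordX`, `coordY`,
#'   `coordZ` (world mm), `diameter_mm`, `probability`, plus voxel-space
#'   `z`, `y`, `x`.
#' @export
sliding_window_detect <- function(vol, model, cfg = inference_config(),
                                  lung_mask = NULL) {
  ps <- cfg$patch_size
  stride <- ps - cfg$patch_overlap
  vd <- dim(vol$voxels)
  oz <- tile_origins_1d(vd[1], ps, stride)
  oy <- tile_origins_1d(vd[2], ps, stride)
  ox <- tile_origins_1d(vd[3], ps, stride)
  mcfg <- model$cfg
  anchors <- enumerate_anchors(lapply(mcfg$pyramid_strides,
                                      function(s) rep(ps, 3L) %/% s),
                               mcfg$pyramid_strides, mcfg$anchor_sizes)
  dets <- list()
  for (z0 in oz) for (y0 in oy) for (x0 in ox) {
    tile <- array(0, dim = rep(ps, 3))
    hi <- pmin(c(z0, y0, x0) + ps, vd)
    tile[seq_len(hi[1] - z0), seq_len(hi[2] - y0), seq_len(hi[3] - x0)] <-
      vol$voxels[(z0 + 1):hi[1], (y0 + 1):hi[2], (x0 + 1):hi[3]]
    out <- forward(model, tile)
    flat <- flatten_head(out)
    prob <- 1 / (1 + exp(-flat$logits))
    keep <- which(prob >= cfg$probability_floor)
    if (length(keep) == 0L) next
    if (length(keep) > cfg$pre_nms_topk)
      keep <- keep[order(-prob[keep])[seq_len(cfg$pre_nms_topk)]]
    kanch <- anchors[keep, , drop = FALSE]
    kreg <- flat$reg[keep, , drop = FALSE]
    dets[[length(dets) + 1L]] <- data.frame(
      z = z0 + kanch$z + kreg[, 1] * kanch$size,
      y = y0 + kanch$y + kreg[, 2] * kanch$size,
      x = x0 + kanch$x + kreg[, 3] * kanch$size,
      diameter = kanch$size * exp(pmin(kreg[, 4], 3)),
      probability = prob[keep])
  }
  dets <- if (length(dets) > 0L) do.call(rbind, dets)
  else data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                  diameter = numeric(0), probability = numeric(0))
  if (nrow(dets) > cfg$pre_nms_topk)
    dets <- dets[order(-dets$probability)[seq_len(cfg$pre_nms_topk)], , drop = FALSE]
  dets <- nms_3d(dets, cfg$nms_iou)
  if (!is.null(lung_mask))
    dets <- mask_filter(dets, lung_mask, margin = cfg$mask_margin)
  if (nrow(dets) > cfg$max_detections_per_scan)
    dets <- dets[seq_len(cfg$max_detections_per_scan), , drop = FALSE]
  world <- voxel_to_world(as.matrix(dets[, c("z", "y", "x")]), vol)
  data.frame(seriesuid = rep(vol$scan_id, nrow(dets)),
             coordX = world[, 1], coordY = world[, 2], coordZ = world[, 3],
             diameter_mm = dets$diameter * mean(vol$spacing),
             probability = dets$probability,
             z = dets$z, y = dets$y, x = dets$x)
}

#' Greedy 3D non-maximum suppression
#'
#' Detections are visited in order of descending probability (ties broken
#' by input order); a detection is suppressed when its cube IoU with any
#' already-kept detection exceeds `nms_iou`.
#'
#' @param dets data frame with `z`, `y`, `x`, `diameter`, `probability`.
#' @param nms_iou suppression threshold.
#' @return The surviving rows, sorted by descending probability.
#' @export
nms_3d <- function(dets, nms_iou = 0.1) {
  if (nrow(dets) <= 1L) return(dets)
  ord <- order(-dets$probability)
  z <- dets$z[ord]; y <- dets$y[ord]; x <- dets$x[ord]
  s <- dets$diameter[ord]
  kept <- integer(0)
  for (j in seq_along(ord)) {
    if (length(kept) > 0L) {
      # vectorised cube IoU of candidate j against all kept detections
      oz <- pmax(pmin(z[j] + s[j] / 2, z[kept] + s[kept] / 2) -
                   pmax(z[j] - s[j] / 2, z[kept] - s[kept] / 2), 0)
      oy <- pmax(pmin(y[j] + s[j] / 2, y[kept] + s[kept] / 2) -
                   pmax(y[j] - s[j] / 2, y[kept] - s[kept] / 2), 0)
      ox <- pmax(pmin(x[j] + s[j] / 2, x[kept] + s[kept] / 2) -
                   pmax(x[j] - s[j] / 2, x[kept] - s[kept] / 2), 0)
      inter <- oz * oy * ox
      if (any(inter / (s[j]^3 + s[kept]^3 - inter) > nms_iou)) next
    }
    kept <- c(kept, j)
  }
  dets[ord[kept], , drop = FALSE]
}

#' Remove extrapulmonary detections
#'
#' Keeps a detection iff its rounded centre voxel lies inside the lung mask
#' dilated by `margin` voxels. With no mask the input passes through with a
#' warning, since masking is optional.
#'
#' @param dets detection data frame with voxel-space `z`, `y`, `x` columns.
#' @param lung_mask binary 3D array on the detection voxel grid.
#' @param margin dilation margin in voxels (city-block metric).
#' @return The filtered data frame.
#' @export
mask_filter <- function(dets, lung_mask, margin = 2L) {
  if (is.null(lung_mask)) {
    warning("no lung mask supplied; detections pass through unfiltered")
    return(dets)
  }
  if (nrow(dets) == 0L) return(dets)
  d <- dim(lung_mask)
  m <- if (margin > 0L)
    dilate3d_cpp(array(lung_mask != 0, dim = d), as.integer(d), as.integer(margin))
  else array(lung_mask != 0, dim = d)
  ijk <- round(as.matrix(dets[, c("z", "y", "x")])) + 1
  inside <- vapply(seq_len(nrow(ijk)), function(i) {
    p <- ijk[i, ]
    if (any(p < 1) || any(p > d)) return(FALSE)
    m[p[1], p[2], p[3]]
  }, logical(1))
  dets[inside, , drop = FALSE]
}

#' Segment the lungs of a CT volume
#'
#' Thresholds below -320 HU, discards air connected to the volume border,
#' keeps the two largest interior air components, and fills enclosed holes
#' (solid nodule cores would otherwise punch holes in the mask). Fully
#' deterministic.
#'
#' @param vol a [ct_volume()] in HU.
#' @param threshold_hu air/tissue threshold.
#' @return Binary 3D array; empty (with a warning) when no interior air
#'   component exists.
#' @export
compute_lung_mask <- function(vol, threshold_hu = -320) {
  v <- vol$voxels
  d <- dim(v)
  air <- array(v < threshold_hu, dim = d)
  lab <- label3d_cpp(air, as.integer(d))
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0]
  interior <- setdiff(unique(lab[lab > 0]), border)
  if (length(interior) == 0L) {
    warning("no interior air component found; returning an empty lung mask")
    return(array(FALSE, dim = d))
  }
  sizes <- table(lab[lab %in% interior])
  keep <- as.integer(names(sort(sizes, decreasing = TRUE)))[seq_len(min(2L, length(sizes)))]
  mask <- array(lab %in% keep, dim = d)
  # fill enclosed cavities: background components not reaching the border
  bg <- label3d_cpp(array(!mask, dim = d), as.integer(d))
  bborder <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  holes <- setdiff(unique(bg[bg > 0]), bborder[bborder > 0])
  if (length(holes) > 0L) mask[bg %in% holes] <- TRUE
  mask
}

#' Write or read detections (LUNA16 submission dialect)
#'
#' Header `seriesuid,coordX,coordY,coordZ,probability` plus an extra
#' `diameter_mm` column.
#'
#' @param dets detection data frame.
#' @param path CSV path.
#' @return `read_detections()` returns the data frame.
#' @export
write_detections <- function(dets, path) {
  cols <- c("seriesuid", "coordX", "coordY", "coordZ", "probability")
  if ("diameter_mm" %in% names(dets)) cols <- c(cols, "diameter_mm")
  write.csv(dets[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) read.csv(path, stringsAsFactors = FALSE)
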