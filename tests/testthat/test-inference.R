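test_that("NMS collapses duplicates, keeps disjoint boxes and is order-free", {
  box <- function(z, p, d = 10) data.frame(z = z, y = 0, x = 0, diameter = d,
                                           probability = p)
  dup <- rbind(box(0, 0.9), box(0, 0.8))
  out <- nms_3d(dup, 0.1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$probability, 0.9)

  far <- rbind(box(0, 0.9), box(100, 0.5), box(200, 0.7))
  expect_identical(nrow(nms_3d(far, 0.1)), 3L)

  # worked example: size-10 cubes at z offsets 0, 2, 30; IoU(1,2) = 2/3
  three <- rbind(box(0, 0.9), box(2, 0.8), box(30, 0.7))
  kept <- nms_3d(three, 0.1)
  expect_equal(sort(kept$z), c(0, 30))
  expect_equal(iou_cube(c(0, 0, 0), 10, c(2, 0, 0), 10), 800 / 1200)

  # permutation invariance for distinct probabilities
  set.seed(17)
  dets <- data.frame(z = runif(12, 0, 40), y = runif(12, 0, 40),
                     x = runif(12, 0, 40), diameter = runif(12, 4, 15),
                     probability = sample(seq(0.1, 0.98, length.out = 12)))
  a <- nms_3d(dets, 0.2)
  perm <- dets[sample(nrow(dets)), ]
  b <- nms_3d(perm, 0.2)
  expect_equal(a[order(a$probability), ], b[order(b$probability), ],
               ignore_attr = TRUE)
})

test_that("mask filtering removes extrapulmonary detections, never adds any", {
  mask <- array(FALSE, dim = c(20, 20, 20))
  mask[8:12, 8:12, 8:12] <- TRUE
  dets <- data.frame(z = c(10, 1, 13), y = c(10, 1, 10), x = c(10, 1, 10),
                     diameter = 5, probability = c(0.9, 0.8, 0.7))
  kept <- mask_filter(dets, mask, margin = 0L)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$z, 10)

  # one voxel outside: removed at margin 0, kept at margin 2
  edge <- data.frame(z = 13, y = 10, x = 10, diameter = 5, probability = 0.5)
  expect_identical(nrow(mask_filter(edge, mask, margin = 0L)), 0L)
  expect_identical(nrow(mask_filter(edge, mask, margin = 2L)), 1L)

  inside <- dets[1, , drop = FALSE]
  expect_identical(mask_filter(inside, mask, margin = 0L), inside)
  expect_warning(pass <- mask_filter(dets, NULL), "unfiltered")
  expect_identical(pass, dets)
})

test_that("computed lung masks recover the phantom lungs and contain all nodules", {
  ph <- small_phantom(seed = 81, n_nodules = 3)
  mask <- compute_lung_mask(ph$volume)
  inter <- sum(mask & ph$lung_mask)
  dice <- 2 * inter / (sum(mask) + sum(ph$lung_mask))
  expect_gt(dice, 0.9)
  for (i in seq_len(nrow(ph$annotations))) {
    v <- round(world_to_voxel(as.numeric(ph$annotations[i, c("coordX", "coordY", "coordZ")]),
                              ph$volume)) + 1
    expect_true(mask[v[1], v[2], v[3]])
  }
  # uniform soft tissue: no air, empty mask with a warning
  flat <- ct_volume(array(40, dim = c(12, 12, 12)))
  expect_warning(m0 <- compute_lung_mask(flat), "empty")
  expect_equal(sum(m0), 0)
})

test_that("single-tile inference equals direct forward+decode and respects the floor", {
  m <- build_model(tiny_model_config(), seed = 12)
  ph <- small_phantom(seed = 91, n_nodules = 1)
  nv <- normalize_hu(ph$volume)
  vol32 <- ct_volume(nv$voxels[1:32, 1:32, 1:32], nv$spacing, nv$origin, "one")
  class(vol32) <- class(nv)
  icfg <- inference_config(patch_size = 32L, patch_overlap = 20L,
                           probability_floor = 1e-3,
                           max_detections_per_scan = 10000L,
                           pre_nms_topk = 100000L)
  dets <- sliding_window_detect(vol32, m, icfg)
  # direct decode of the same tile
  out <- forward(m, vol32$voxels)
  flat <- lungrpn:::flatten_head(out)
  anchors <- enumerate_anchors(lapply(c(2L, 4L, 8L), function(s) rep(32L, 3) %/% s))
  prob <- 1 / (1 + exp(-flat$logits))
  keep <- which(prob >= 1e-3)
  manual <- data.frame(z = anchors$z[keep] + flat$reg[keep, 1] * anchors$size[keep],
                       probability = prob[keep])
  manual_nms <- nms_3d(cbind(manual,
                             y = anchors$y[keep] + flat$reg[keep, 2] * anchors$size[keep],
                             x = anchors$x[keep] + flat$reg[keep, 3] * anchors$size[keep],
                             diameter = anchors$size[keep] * exp(pmin(flat$reg[keep, 4], 3))),
                       icfg$nms_iou)
  expect_identical(nrow(dets), nrow(manual_nms))
  expect_equal(sort(dets$probability), sort(manual_nms$probability))

  # probability floor 1 on an untrained model: nothing survives
  icfg2 <- inference_config(patch_size = 32L, patch_overlap = 20L,
                            probability_floor = 1)
  expect_identical(nrow(sliding_window_detect(vol32, m, icfg2)), 0L)

  # end-to-end determinism
  d2 <- sliding_window_detect(vol32, m, icfg)
  expect_identical(dets, d2)
})

test_that("volumes smaller than a tile are padded and boundary nodules tiled over", {
  m <- build_model(tiny_model_config(), seed = 13)
  small <- ct_volume(array(runif(24 * 24 * 24), dim = c(24, 24, 24)))
  class(small) <- c("normalized_volume", class(small))
  icfg <- inference_config(patch_size = 32L, patch_overlap = 20L,
                           probability_floor = 0.5)
  expect_no_error(sliding_window_detect(small, m, icfg))

  # a tile origin grid always covers the last voxels (overlap contract)
  org <- lungrpn:::tile_origins_1d(80L, 64L, 40L)
  expect_true(max(org) + 64L >= 80L)
  expect_identical(org[1], 0L)
  org2 <- lungrpn:::tile_origins_1d(200L, 64L, 44L)
  expect_true(all(diff(org2) <= 44L))
  expect_true(max(org2) + 64L >= 200L)
})

test_that("detections CSV round trips in the submission dialect", {
  dets <- data.frame(seriesuid = c("a", "b"), coordX = c(1.5, 2.5),
                     coordY = c(-3, 4), coordZ = c(10, 20),
                     probability = c(0.9, 0.2), diameter_mm = c(6, 11))
  path <- file.path(withr::local_tempdir(), "dets.csv")
  write_detections(dets, path)
  expect_identical(readLines(path)[1],
                   "seriesuid,coordX,coordY,coordZ,probability,diameter_mm")
  back <- read_detections(path)
  expect_equal(back$probability, dets$probability)
  expect_equal(back$coordX, dets$coordX)
})
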