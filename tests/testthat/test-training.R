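make_head_like <- function(level_dims, logit = -4) {
  lapply(level_dims, function(d) {
    a <- array(0, dim = c(d, 15L))
    a[, , , 1:3] <- logit
    a
  })
}

test_that("focal classification matches the closed form on a single anchor", {
  # one grid cell at the coarsest possible resolution: craft a head output
  # with a single-level 1x1x1 grid (3 anchors)
  anchors <- enumerate_anchors(list(c(1L, 1L, 1L)), strides = 8L)
  gts <- data.frame(z = 4, y = 4, x = 4, diameter = 10)
  asg <- assign_nearest(anchors, gts, ignore_iou = 0)   # non-positives ignored
  expect_identical(sum(asg$label == "positive"), 1L)
  expect_true(all(asg$label[asg$label != "positive"] == "ignore"))
  logit <- 0.4
  head <- list(array(0, dim = c(1, 1, 1, 15)))
  head[[1]][1, 1, 1, 1:3] <- logit
  # perfect regression for the positive anchor
  pos <- which(asg$label == "positive")
  tgt <- as.numeric(asg[pos, c("dz", "dy", "dx", "dd")])
  a_idx <- which(c(5, 10, 20) == asg$size[pos])
  head[[1]][1, 1, 1, 3 + (a_idx - 1) * 4 + 1:4] <- tgt
  ls <- detection_loss(head, asg, alpha = 0.25, gamma = 2)
  p <- 1 / (1 + exp(-logit))
  expect_equal(ls$cls, -0.25 * (1 - p)^2 * log(p), tolerance = 1e-9)
  expect_equal(ls$reg, 0)

  # perfect logits drive the loss to (near) zero
  head2 <- head
  head2[[1]][1, 1, 1, 1:3] <- -40
  head2[[1]][1, 1, 1, a_idx] <- 40
  ls2 <- detection_loss(head2, asg)
  expect_lt(ls2$total, 1e-3)
})

test_that("ignored anchors contribute nothing to value or gradient", {
  level_dims <- list(c(4L, 4L, 4L), c(2L, 2L, 2L), c(1L, 1L, 1L))
  anchors <- enumerate_anchors(level_dims)
  gts <- data.frame(z = 3.2, y = 3.1, x = 2.9, diameter = 5)
  asg <- assign_nearest(anchors, gts)
  ign <- which(asg$label == "ignore")
  expect_gt(length(ign), 0L)
  set.seed(16)
  head <- lapply(level_dims, function(d) array(rnorm(prod(d) * 15), c(d, 15L)))
  base <- detection_loss(head, asg)
  # perturb logits of ignored anchors arbitrarily via the flat mapping
  flat <- lungrpn:::flatten_head(head)
  flat$logits[ign] <- flat$logits[ign] + rnorm(length(ign), sd = 50)
  mod <- lungrpn:::unflatten_grad(flat$logits, flat$reg, level_dims)
  # unflatten_grad rebuilds arrays in head layout, reuse as a head output
  pert <- detection_loss(mod, asg)
  expect_equal(pert$total, base$total, tolerance = 1e-12)
})

test_that("augmentation is seeded, identity-able, and moves geometry with voxels", {
  ph <- small_phantom(seed = 51, n_nodules = 1)
  nv <- normalize_hu(ph$volume)
  p <- sample_training_patches(nv, ph$annotations,
                               preprocess_config(patch_size = 32L,
                                                 patches_per_scan = 1L,
                                                 positive_fraction = 1),
                               seed = 3)[[1]]
  # identity draw leaves everything untouched
  id_cfg <- augment_config(flip_xy = FALSE, rotate_z = c(0, 0), scale = c(1, 1))
  same <- augment(p, id_cfg, seed = 4)
  expect_identical(same$voxels, p$voxels)
  expect_identical(same$annotations, p$annotations)

  cfg <- augment_config()
  a1 <- augment(p, cfg, seed = 5)
  a2 <- augment(p, cfg, seed = 5)
  expect_identical(a1$voxels, a2$voxels)
  expect_identical(a1$annotations, a2$annotations)
  expect_true(all(a1$voxels >= 0 & a1$voxels <= 1))

  # pure scaling: diameter multiplies, centre scales about the patch centre
  sc_cfg <- augment_config(flip_xy = FALSE, rotate_z = c(0, 0),
                           scale = c(1.25, 1.25))
  sc <- augment(p, sc_cfg, seed = 6)
  expect_equal(sc$annotations$diameter, p$annotations$diameter * 1.25)
  centre <- (dim(p$voxels) - 1) / 2
  want <- (as.numeric(p$annotations[1, c("z", "y", "x")]) - centre) * 1.25 + centre
  expect_equal(as.numeric(sc$annotations[1, c("z", "y", "x")]), want)

  # integer-exact flips: transforming voxels then assigning anchors equals
  # flipping the annotation and assigning on the flipped patch
  fl_cfg <- augment_config(flip_xy = TRUE, rotate_z = c(0, 0), scale = c(1, 1))
  fl <- NULL
  for (s in 1:20) {                 # find a seed that actually flips
    cand <- augment(p, fl_cfg, seed = s)
    if (!identical(cand$voxels, p$voxels)) { fl <- cand; break }
  }
  expect_false(is.null(fl))
  anchors <- enumerate_anchors(lapply(c(2L, 4L, 8L), function(s) rep(32L, 3) %/% s))
  asg_fl <- assign_nearest(anchors, fl$annotations)
  expect_identical(sum(asg_fl$label == "positive"), nrow(fl$annotations))
})

test_that("training reduces the loss, is deterministic, and centralization only reroutes updates", {
  ph <- small_phantom(seed = 61, n_nodules = 2)
  nv <- normalize_hu(ph$volume)
  patches <- sample_training_patches(nv, ph$annotations,
                                     preprocess_config(patch_size = 32L,
                                                       patches_per_scan = 4L,
                                                       positive_fraction = 1),
                                     seed = 7)
  cfg <- tiny_model_config()
  tc <- train_config(epochs = 8L, batch_size = 2L, seed = 11L)
  m1 <- train(build_model(cfg, seed = 1), patches, tc)
  expect_lt(m1$history$loss[8], m1$history$loss[1])
  expect_true(all(is.finite(m1$history$loss)))
  expect_true(all(m1$history$loss >= 0))

  m2 <- train(build_model(cfg, seed = 1), patches, tc)
  expect_identical(m1$history, m2$history)

  # gradient centralization: same first-step loss (it only alters updates),
  # different trajectory afterwards
  tc_nogc <- train_config(epochs = 8L, batch_size = 2L, seed = 11L,
                          grad_centralization = FALSE)
  m3 <- train(build_model(cfg, seed = 1), patches, tc_nogc)
  expect_equal(attr(m3$history, "first_step_loss"),
               attr(m1$history, "first_step_loss"))
  expect_false(identical(m1$history$loss, m3$history$loss))
})

test_that("trained checkpoints reproduce detections exactly", {
  ph <- small_phantom(seed = 71, n_nodules = 1)
  nv <- normalize_hu(ph$volume)
  patches <- sample_training_patches(nv, ph$annotations,
                                     preprocess_config(patch_size = 32L,
                                                       patches_per_scan = 2L,
                                                       positive_fraction = 1),
                                     seed = 8)
  m <- train(build_model(tiny_model_config(), seed = 2), patches,
             train_config(epochs = 2L, batch_size = 2L, seed = 3L))
  icfg <- inference_config(patch_size = 32L, patch_overlap = 20L,
                           probability_floor = 1e-4)
  d1 <- sliding_window_detect(nv, m, icfg, lung_mask = ph$lung_mask)
  path <- file.path(withr::local_tempdir(), "trained.rds")
  save_checkpoint(m, path)
  d2 <- sliding_window_detect(nv, load_checkpoint(path), icfg,
                              lung_mask = ph$lung_mask)
  expect_identical(d1, d2)
})
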