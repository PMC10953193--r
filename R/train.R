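#' Training configuration
#'
#' Defaults follow the reference training recipe: Ranger (RAdam + Lookahead)
#' with gradient centralization, learning rate 0.001, and focal-loss
#' parameters from the RetinaNet lineage. The epoch default of 200 matches
#' the full-scale recipe; desk-scale runs pass something far smaller.
#'
#' @param optimizer `"ranger"` or `"adam"` (fallback without rectification,
#'   lookahead or gradient centralization).
#' @param learning_rate constant step size.
#' @param epochs passes over the patch set.
#' @param batch_size patches per optimiser step (gradients averaged).
#' @param focal_alpha,focal_gamma focal-loss shape.
#' @param lambda regression-term weight.
#' @param grad_centralization subtract the per-filter gradient mean from
#'   convolution weight gradients before the optimiser step.
#' @param seed master seed for shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("ranger", "adam"), learning_rate = 0.001,
                         epochs = 200L, batch_size = 4L,
                         focal_alpha = 0.25, focal_gamma = 2, lambda = 1,
                         grad_centralization = TRUE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 lambda = lambda, grad_centralization = isTRUE(grad_centralization),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Augmentation configuration
#'
#' Random flips in the xy plane, rotation about the z axis uniform over
#' `rotate_z` degrees, and isotropic scaling uniform over `scale`. Setting
#' `flip_xy = FALSE`, `rotate_z = c(0, 0)` and `scale = c(1, 1)` disables
#' augmentation exactly (the identity draw skips resampling).
#'
#' @param flip_xy allow random flips of the x and y axes.
#' @param rotate_z rotation range about z, degrees.
#' @param scale isotropic scale-factor range; diameters scale with it.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_xy = TRUE, rotate_z = c(0, 180),
                           scale = c(0.75, 1.25)) {
  if (any(scale <= 0)) stop("scale bounds must be positive")
  structure(list(flip_xy = isTRUE(flip_xy), rotate_z = rotate_z, scale = scale),
            class = "augment_config")
}

#' Augment a training patch
#'
#' The same spatial transform is applied to the voxels (trilinear
#' interpolation about the patch centre) and, exactly, to the annotation
#' centres; diameters are multiplied by the scale factor (a sphere's
#' diameter is rotation- and flip-invariant). Annotations pushed outside the
#' patch are dropped with a message. Intensities stay in `[0, 1]` because
#' trilinear interpolation is convex.
#'
#' @param patch a patch from [sample_training_patches()].
#' @param cfg an [augment_config()].
#' @param seed integer seed; identical seeds give identical outputs.
#' @return The transformed patch (same structure).
#' @export
augment <- function(patch, cfg = augment_config(), seed = 1L) {
  set.seed(as.integer(seed))
  flips <- if (cfg$flip_xy) runif(2) < 0.5 else c(FALSE, FALSE)
  angle <- runif(1, cfg$rotate_z[1], cfg$rotate_z[2]) * pi / 180
  scale <- runif(1, cfg$scale[1], cfg$scale[2])

  d <- dim(patch$voxels)
  centre <- (d - 1) / 2
  if (!flips[1] && !flips[2] && angle == 0 && scale == 1) return(patch)

  if (angle == 0 && scale == 1) {
    # pure flips are exact array reversals; skip trilinear resampling
    vox <- patch$voxels
    if (flips[1]) vox <- vox[, d[2]:1, , drop = FALSE]
    if (flips[2]) vox <- vox[, , d[3]:1, drop = FALSE]
    anns <- patch$annotations
    if (nrow(anns) > 0L) {
      if (flips[1]) anns$y <- (d[2] - 1) - anns$y
      if (flips[2]) anns$x <- (d[3] - 1) - anns$x
    }
    out <- patch
    out$voxels <- vox
    out$annotations <- anns
    return(out)
  }

  # forward transform (z, y, x): flip signs on y/x, rotate about z in the
  # (y, x) plane, then scale isotropically about the patch centre
  ca <- cos(angle); sa <- sin(angle)
  Fwd <- diag(3)
  Fwd[2, 2] <- ifelse(flips[1], -1, 1)
  Fwd[3, 3] <- ifelse(flips[2], -1, 1)
  R <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Fwd <- scale * R %*% Fwd
  Inv <- solve(Fwd)

  vox <- affine_sample_cpp(patch$voxels, as.integer(d), as.numeric(t(Inv)),
                           centre, 0)
  anns <- patch$annotations
  if (nrow(anns) > 0L) {
    pts <- t(Fwd %*% (t(as.matrix(anns[, c("z", "y", "x")])) - centre) + centre)
    inside <- apply(pts, 1, function(p) all(p >= 0 & p <= d - 1))
    if (any(!inside))
      message(sum(!inside), " annotation(s) left the patch under augmentation")
    anns <- data.frame(z = pts[inside, 1], y = pts[inside, 2],
                       x = pts[inside, 3],
                       diameter = anns$diameter[inside] * scale)
  }
  out <- patch
  out$voxels <- vox
  out$annotations <- anns
  out
}

#' Train the detector
#'
#' Runs the focal-loss / smooth-L1 objective over the patch set with the
#' configured optimiser and anchor-assignment rule. Assignments are
#' recomputed after each augmentation draw. Training is fully seeded:
#' identical inputs, configuration and seed give an identical loss history
#' and final weights.
#'
#' @param model an `rpn3d_model` from [build_model()].
#' @param patches list of patches from [sample_training_patches()].
#' @param train_cfg a [train_config()].
#' @param augment_cfg an [augment_config()], or `NULL` for no augmentation.
#' @param assigner `"nearest"` or `"iou"` training-sample selection.
#' @param verbose print a per-epoch summary line.
#' @return The model, with `model$history` set to a data frame of per-epoch
#'   mean losses (`epoch`, `loss`, `cls`, `reg`) carrying the first-step
#'   loss as attribute `first_step_loss`.
#' @export
train <- function(model, patches, train_cfg = train_config(),
                  augment_cfg = NULL, assigner = c("nearest", "iou"),
                  verbose = FALSE) {
  assigner <- match.arg(assigner)
  if (length(patches) < 1L) stop("need at least one training patch")
  set.seed(train_cfg$seed)
  opt <- optim_new(model$params, lr = train_cfg$learning_rate,
                   optimizer = train_cfg$optimizer,
                   grad_centralization = train_cfg$grad_centralization)
  cfg <- model$cfg
  anchor_cache <- new.env(parent = emptyenv())
  anchors_for <- function(d) {
    key <- paste(d, collapse = "x")
    if (is.null(anchor_cache[[key]]))
      anchor_cache[[key]] <- enumerate_anchors(
        lapply(cfg$pyramid_strides, function(s) d %/% s),
        cfg$pyramid_strides, cfg$anchor_sizes)
    anchor_cache[[key]]
  }
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        cls = numeric(0), reg = numeric(0))
  # without augmentation the patch geometry never changes, so the anchor
  # assignment of each patch can be computed once
  static_asg <- if (is.null(augment_cfg))
    lapply(patches, function(p) {
      a <- anchors_for(dim(p$voxels))
      if (assigner == "nearest") assign_nearest(a, p$annotations)
      else assign_iou(a, p$annotations)
    })
  first_step_loss <- NA_real_
  step <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample(seq_along(patches))
    ep <- c(loss = 0, cls = 0, reg = 0)
    nb <- 0L
    for (start in seq(1, length(ord), by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      zero_grads(model$params)
      bl <- c(loss = 0, cls = 0, reg = 0)
      for (i in idx) {
        patch <- patches[[i]]
        if (!is.null(augment_cfg)) {
          step_seed <- (train_cfg$seed * 7919L + epoch * 1009L + i) %%
            .Machine$integer.max
          patch <- augment(patch, augment_cfg, seed = step_seed)
          anchors <- anchors_for(dim(patch$voxels))
          assignment <- if (assigner == "nearest")
            assign_nearest(anchors, patch$annotations)
          else assign_iou(anchors, patch$annotations)
        } else {
          assignment <- static_asg[[i]]
        }
        out <- forward(model, patch$voxels)
        ls <- detection_loss(out, assignment, alpha = train_cfg$focal_alpha,
                             gamma = train_cfg$focal_gamma,
                             lambda = train_cfg$lambda, with_grad = TRUE)
        if (!is.finite(ls$total))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        backward(model, ls$grad)
        bl <- bl + c(ls$total, ls$cls, ls$reg)
      }
      step <- step + 1L
      if (is.na(first_step_loss)) first_step_loss <- bl[["loss"]] / length(idx)
      opt <- optim_step(opt, grad_scale = 1 / length(idx))
      ep <- ep + bl / length(idx)
      nb <- nb + 1L
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = ep[["loss"]] / nb,
                                         cls = ep[["cls"]] / nb,
                                         reg = ep[["reg"]] / nb))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  cls %.5f  reg %.5f",
                      epoch, ep[["loss"]] / nb, ep[["cls"]] / nb, ep[["reg"]] / nb))
  }
  attr(history, "first_step_loss") <- first_step_loss
  model$history <- history
  model
}
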