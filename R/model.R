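#' Detector configuration
#'
#' Describes the 3D region proposal network: a three-stage backbone
#' (`resnet`, `resnext` or `csp_resnext`), an optional feature-pyramid neck,
#' and one dense head per pyramid level. Levels sit at strides 2, 4 and 8
#' relative to the input patch; every level carries all three cubic anchors
#' (5, 10 and 20 voxels), and each head emits 15 channels per grid cell:
#' 3 anchors x (probability logit, z, y, x offsets, log-diameter).
#'
#' @param backbone_variant one of `"resnet"`, `"resnext"`, `"csp_resnext"`.
#' @param use_fpn logical; `TRUE` adds the top-down fusion neck, `FALSE`
#'   passes per-level lateral features straight to the heads.
#' @param base_channels stem width; stage widths are 2x, 4x and 8x this.
#'   Must be even for the CSP variant (channels are split in half).
#' @param cardinality group count for the grouped 3x3x3 convolution in
#'   ResNeXt paths; reduced automatically to the largest divisor of the
#'   bottleneck width.
#' @param stage_blocks integer length-3, residual blocks per stage.
#' @param neck_channels width of the lateral/fused feature maps and heads;
#'   defaults to `base_channels`.
#' @return A `model_config` list.
#' @export
model_config <- function(backbone_variant = c("csp_resnext", "resnet", "resnext"),
                         use_fpn = TRUE, base_channels = 8L, cardinality = 8L,
                         stage_blocks = c(1L, 1L, 1L), neck_channels = NULL) {
  backbone_variant <- match.arg(backbone_variant)
  base_channels <- as.integer(base_channels)
  if (backbone_variant == "csp_resnext" && base_channels %% 2L != 0L)
    stop("csp_resnext requires an even base_channels (channel split)")
  if (length(stage_blocks) != 3L || any(stage_blocks < 1L))
    stop("stage_blocks must be 3 positive integers")
  if (is.null(neck_channels)) neck_channels <- base_channels
  structure(list(backbone_variant = backbone_variant,
                 use_fpn = isTRUE(use_fpn),
                 base_channels = base_channels,
                 cardinality = as.integer(cardinality),
                 stage_blocks = as.integer(stage_blocks),
                 neck_channels = as.integer(neck_channels),
                 pyramid_strides = c(2L, 4L, 8L),
                 anchor_sizes = c(5, 10, 20),
                 anchors_per_level = 3L),
            class = "model_config")
}

# largest divisor of n not exceeding g
group_count <- function(n, g) { for (d in min(g, n):1) if (n %% d == 0) return(d); 1L }

conv_norm_relu <- function(cin, cout, k = 3L, stride = 1L, groups = 1L)
  mod_seq(mod_conv(cin, cout, k = k, stride = stride, groups = groups),
          mod_inorm(cout), mod_relu())

block_resnet <- function(C, cfg)
  mod_residual(mod_seq(mod_conv(C, C, 3L), mod_inorm(C), mod_relu(),
                       mod_conv(C, C, 3L), mod_inorm(C)))

resnext_unit <- function(C, cfg) {
  mid <- max(1L, C %/% 2L)
  g <- group_count(mid, cfg$cardinality)
  mod_residual(mod_seq(mod_conv(C, mid, 1L), mod_inorm(mid), mod_relu(),
                       mod_conv(mid, mid, 3L, groups = g), mod_inorm(mid), mod_relu(),
                       mod_conv(mid, C, 1L), mod_inorm(C)))
}

block_csp_resnext <- function(C, cfg) {
  half <- C %/% 2L
  mod_csp(C, resnext_unit(half, cfg),
          mod_seq(mod_conv(C, C, 1L), mod_inorm(C), mod_relu()))
}

#' Build a CSP-ResNeXt grouped residual block
#'
#' Exposed primarily so the block's wiring is testable in isolation: the
#' input is split 50/50 along channels, the first half runs through a
#' grouped-convolution ResNeXt residual unit, the halves are concatenated,
#' and a 1x1x1 transition convolution fuses them. Spatial shape is
#' preserved.
#'
#' @param channels even channel count.
#' @param cardinality target group count for the grouped convolution.
#' @param seed RNG seed for weight initialisation.
#' @return A module (environment) with `fwd`, `bwd` and `param_list`.
#' @export
csp_resnext_block <- function(channels, cardinality = 8L, seed = NULL) {
  if (channels %% 2L != 0L)
    stop("CSP block needs an even channel count, got ", channels)
  if (!is.null(seed)) set.seed(seed)
  block_csp_resnext(as.integer(channels),
                    list(cardinality = as.integer(cardinality)))
}

#' Build the 3D region proposal network
#'
#' Assembles stem, three downsampling stages of the configured backbone
#' variant, the neck (lateral 1x1x1 projections, optionally fused top-down)
#' and one detection head per level. The three variants share the stage
#' interface, so they are interchangeable behind the same neck and heads.
#' The head's probability-logit biases are initialised to -4 so that the
#' initial foreground probability is low, as is usual for focal-loss dense
#' detectors.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for weight initialisation (builds are deterministic
#'   given it).
#' @return An `rpn3d_model` environment; call [forward()] to run it.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(as.integer(seed))
  C <- cfg$base_channels
  widths <- C * c(2L, 4L, 8L)
  F <- cfg$neck_channels
  block_fn <- switch(cfg$backbone_variant,
                     resnet = block_resnet,
                     resnext = resnext_unit,
                     csp_resnext = block_csp_resnext,
                     stop("unknown backbone variant: ", cfg$backbone_variant))
  self <- new.env(parent = emptyenv())
  self$cfg <- cfg
  self$build_seed <- as.integer(seed)
  # the stem itself carries the first stride-2 downsampling, so no feature
  # map is ever at full patch resolution
  self$stem <- mod_seq(mod_conv(1L, widths[1], 3L, 2L, need_dx = FALSE),
                       mod_inorm(widths[1]), mod_relu())
  self$stages <- lapply(1:3, function(i) {
    mods <- if (i == 1L) list()
    else list(conv_norm_relu(widths[i - 1L], widths[i], 3L, 2L))
    for (b in seq_len(cfg$stage_blocks[i])) mods <- c(mods, list(block_fn(widths[i], cfg)))
    mod_seq(mods)
  })
  self$lats <- lapply(1:3, function(i) conv_norm_relu(widths[i], F, 1L))
  if (cfg$use_fpn) {
    self$smooths <- lapply(1:3, function(i) conv_norm_relu(F, F, 3L))
    self$ups <- lapply(1:2, function(i) mod_upsample2())
  }
  self$heads <- lapply(1:3, function(i) {
    final <- mod_conv(F, 15L, 1L)
    # foreground prior ~0.25%: with ~10^5 anchors per patch this keeps the
    # initial negative focal pressure negligible, so no steps are spent on
    # a global suppression phase
    final$b[1:3] <- -6
    mod_seq(mod_conv(F, F, 3L), mod_inorm(F), mod_relu(), final)
  })
  mods <- c(list(self$stem), self$stages, self$lats,
            if (cfg$use_fpn) self$smooths else list(), self$heads)
  self$params <- collect_params(mods)
  class(self) <- "rpn3d_model"
  self
}

#' @export
print.rpn3d_model <- function(x, ...) {
  cat(sprintf("<rpn3d_model> %s%s, base %d, %s parameters\n",
              x$cfg$backbone_variant, if (x$cfg$use_fpn) " + FPN" else "",
              x$cfg$base_channels, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Run the detector on a patch
#'
#' @param model an `rpn3d_model` from [build_model()].
#' @param patch 3D array (values in `[0, 1]`), each spatial dimension
#'   divisible by 8 (the largest pyramid stride).
#' @return List of three head outputs, one per pyramid level: arrays of
#'   shape `(Z/s, Y/s, X/s, 15)` for strides s = 2, 4, 8.
#' @export
forward <- function(model, patch) {
  d <- dim(patch)
  if (length(d) != 3L) stop("patch must be a 3D array")
  if (any(d %% 8L != 0L))
    stop("patch dimensions (", paste(d, collapse = "x"),
         ") must be divisible by 8, the largest pyramid stride")
  x <- model$stem$fwd(as_fmap(patch))
  c1 <- model$stages[[1]]$fwd(x)
  c2 <- model$stages[[2]]$fwd(c1)
  c3 <- model$stages[[3]]$fwd(c2)
  l1 <- model$lats[[1]]$fwd(c1)
  l2 <- model$lats[[2]]$fwd(c2)
  l3 <- model$lats[[3]]$fwd(c3)
  if (model$cfg$use_fpn) {
    p3 <- l3
    p2 <- l2 + model$ups[[2]]$fwd(p3)
    p1 <- l1 + model$ups[[1]]$fwd(p2)
    f <- list(model$smooths[[1]]$fwd(p1), model$smooths[[2]]$fwd(p2),
              model$smooths[[3]]$fwd(p3))
  } else {
    f <- list(l1, l2, l3)
  }
  lapply(1:3, function(i) model$heads[[i]]$fwd(f[[i]]))
}

# Reverse pass: takes per-level gradients w.r.t. the head outputs and
# accumulates parameter gradients; returns the input gradient (unused by
# training but handy for checks).
backward <- function(model, dhead) {
  df <- lapply(1:3, function(i) model$heads[[i]]$bwd(dhead[[i]]))
  if (model$cfg$use_fpn) {
    dp1 <- model$smooths[[1]]$bwd(df[[1]])
    dl1 <- dp1
    dp2 <- model$smooths[[2]]$bwd(df[[2]]) + model$ups[[1]]$bwd(dp1)
    dl2 <- dp2
    dp3 <- model$smooths[[3]]$bwd(df[[3]]) + model$ups[[2]]$bwd(dp2)
    dl3 <- dp3
  } else {
    dl1 <- df[[1]]; dl2 <- df[[2]]; dl3 <- df[[3]]
  }
  dc3 <- model$lats[[3]]$bwd(dl3)
  dc2 <- model$lats[[2]]$bwd(dl2) + model$stages[[3]]$bwd(dc3)
  dc1 <- model$lats[[1]]$bwd(dl1) + model$stages[[2]]$bwd(dc2)
  dx <- model$stem$bwd(model$stages[[1]]$bwd(dc1))
  dx
}

# Flatten per-level head outputs into vectors aligned with
# enumerate_anchors(): level-major, grid cells in (z fastest) linear order,
# the 3 anchor sizes contiguous within each cell.
flatten_head <- function(head_out) {
  logits <- list(); reg <- list()
  for (lv in seq_along(head_out)) {
    arr <- head_out[[lv]]
    n <- prod(dim(arr)[1:3])
    m <- arr; dim(m) <- c(n, 15L)
    logits[[lv]] <- as.vector(t(m[, 1:3, drop = FALSE]))
    r <- array(m[, 4:15], dim = c(n, 4L, 3L))      # [cell, component, anchor]
    reg[[lv]] <- sapply(1:4, function(j) as.vector(t(r[, j, ])))
  }
  list(logits = unlist(logits), reg = do.call(rbind, reg))
}

# Inverse of flatten_head for gradients.
unflatten_grad <- function(dlogits, dreg, level_dims) {
  out <- list(); ofs <- 0L
  for (lv in seq_along(level_dims)) {
    sdim <- level_dims[[lv]]
    n <- prod(sdim)
    g <- matrix(0, n, 15L)
    idx <- ofs + seq_len(3L * n)
    g[, 1:3] <- matrix(dlogits[idx], n, 3L, byrow = TRUE)
    for (j in 1:4) {
      comp <- matrix(dreg[idx, j], n, 3L, byrow = TRUE)   # [cell, anchor]
      g[, 3L + j + 4L * (0:2)] <- comp
    }
    dim(g) <- c(sdim, 15L)
    out[[lv]] <- g
    ofs <- ofs + 3L * n
  }
  out
}

#' Save or load a model checkpoint
#'
#' A checkpoint stores the configuration, build seed and every parameter
#' value; loading rebuilds the model and restores bit-identical inference
#' behaviour.
#'
#' @param model an `rpn3d_model`.
#' @param path file path (RDS).
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(model$params, function(p) get(p$value, envir = p$env))
  saveRDS(list(cfg = model$cfg, seed = model$build_seed, values = values,
               history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, seed = ck$seed)
  stopifnot(length(model$params) == length(ck$values))
  for (i in seq_along(ck$values))
    assign(model$params[[i]]$value, ck$values[[i]],
           envir = model$params[[i]]$env)
  model$history <- ck$history
  model
}
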