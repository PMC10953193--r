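#' Preprocessing configuration
#'
#' Parameters for the standard CT preprocessing chain: isotropic resampling,
#' Hounsfield-window normalisation, and training-patch extraction. Defaults
#' follow common practice for low-dose chest CT nodule detection: a window of
#' -1200 to 600 HU mapped linearly onto `[0, 1]` and a 1 mm isotropic grid.
#'
#' @param hu_min,hu_max Hounsfield window bounds; values outside are clipped.
#' @param target_spacing mm per axis `(z, y, x)` after resampling.
#' @param patch_size cubic training-patch edge in voxels; must be at least
#'   the largest anchor size (20).
#' @param patches_per_scan number of training patches sampled per scan.
#' @param positive_fraction fraction of patches centred on a nodule.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(hu_min = -1200, hu_max = 600,
                              target_spacing = c(1, 1, 1),
                              patch_size = 64L, patches_per_scan = 8L,
                              positive_fraction = 0.75) {
  if (hu_min >= hu_max) stop("hu_min must be < hu_max")
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(target_spacing <= 0)) stop("target_spacing components must be > 0")
  if (patch_size < 20L) stop("patch_size must be >= the largest anchor size (20)")
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must lie in [0, 1]")
  structure(list(hu_min = hu_min, hu_max = hu_max,
                 target_spacing = target_spacing,
                 patch_size = as.integer(patch_size),
                 patches_per_scan = as.integer(patches_per_scan),
                 positive_fraction = positive_fraction),
            class = "preprocess_config")
}

# round half away from zero, unlike base round()'s round-half-even:
# deterministic grid sizes across platforms.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Output grid shape of isotropic resampling
#'
#' @param shape integer length-3 input shape `(z, y, x)`.
#' @param spacing input spacing, mm per axis `(z, y, x)`.
#' @param target_spacing output spacing, mm per axis.
#' @return Integer length-3 output shape, `round(shape * spacing / target)`
#'   with half-away-from-zero rounding.
#' @export
resampled_shape <- function(shape, spacing, target_spacing = c(1, 1, 1)) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  as.integer(round_half_up(shape * spacing / target_spacing))
}

#' Resample a CT volume to isotropic spacing
#'
#' Trilinear interpolation onto a grid with `cfg$target_spacing`. The world
#' origin is preserved; output shape follows [resampled_shape()]. Because
#' voxel indices address voxel centres and both grids share the origin, a
#' volume already at target spacing is returned voxel-identical.
#'
#' @param vol a [ct_volume()].
#' @param cfg a [preprocess_config()].
#' @return A [ct_volume()] on the isotropic grid.
#' @export
resample_isotropic <- function(vol, cfg = preprocess_config()) {
  in_dim <- dim(vol$voxels)
  if (any(in_dim < 2L))
    stop("cannot resample a degenerate axis (size < 2): shape ",
         paste(in_dim, collapse = "x"))
  target <- cfg$target_spacing
  if (isTRUE(all.equal(vol$spacing, target)))
    return(ct_volume(vol$voxels, target, vol$origin, vol$scan_id))
  out_dim <- resampled_shape(in_dim, vol$spacing, target)
  scale <- target / vol$spacing
  out <- resample_grid_cpp(vol$voxels, as.integer(in_dim), scale,
                           as.integer(out_dim))
  ct_volume(out, spacing = target, origin = vol$origin, scan_id = vol$scan_id)
}

#' Round to single precision
#'
#' Normalised volumes are stored as single-precision floats; R has no native
#' float32 array, so values are passed through a float round trip to make the
#' in-memory representation bit-equal to what any float32 consumer would see.
#'
#' @param x numeric vector or array.
#' @return `x` with every value rounded to the nearest float32.
#' @export
as_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               "double", n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' Normalise Hounsfield units to [0, 1]
#'
#' Linear map of the HU window onto `[0, 1]` with clipping:
#' `value = clip((HU - hu_min) / (hu_max - hu_min), 0, 1)`, stored at
#' single precision. With the default window, -1200 HU maps to 0 and
#' 600 HU to 1.
#'
#' @inheritParams resample_isotropic
#' @return A `normalized_volume`: like a [ct_volume()] but with voxels in
#'   `[0, 1]`.
#' @export
normalize_hu <- function(vol, cfg = preprocess_config()) {
  v <- (vol$voxels - cfg$hu_min) / (cfg$hu_max - cfg$hu_min)
  v[v < 0] <- 0
  v[v > 1] <- 1
  out <- ct_volume(as_single(v), vol$spacing, vol$origin, vol$scan_id)
  class(out) <- c("normalized_volume", class(out))
  out
}

#' Sample training patches from a normalised volume
#'
#' Positive patches are centred on a randomly chosen annotated nodule with
#' uniform integer jitter up to `patch_size / 4` per axis; negative patches
#' are placed uniformly inside the lung bounding box (or the whole volume
#' when no mask is given). Patches extending past the volume are zero-padded.
#' Annotation centres are re-expressed in patch-local voxel coordinates;
#' diameters are in voxels (equal to mm on the 1 mm grid).
#'
#' @param vol a `normalized_volume`.
#' @param annotations data frame with LUNA16-style columns `seriesuid`,
#'   `coordX`, `coordY`, `coordZ`, `diameter_mm` (world mm).
#' @param cfg a [preprocess_config()].
#' @param seed integer seed; identical seeds give identical patches.
#' @param lung_mask optional binary array on the same grid, used to bound
#'   negative-patch placement.
#' @return List of patches; each has `voxels` (cubic array), `origin_voxel`
#'   (0-based `(z, y, x)` of the patch corner in the volume), `annotations`
#'   (data frame `z, y, x, diameter` in patch-local voxels), and `positive`.
#' @export
sample_training_patches <- function(vol, annotations, cfg = preprocess_config(),
                                    seed = 1L, lung_mask = NULL) {
  set.seed(as.integer(seed))
  ps <- cfg$patch_size
  vd <- dim(vol$voxels)
  n <- cfg$patches_per_scan
  anns <- annotations[annotations$seriesuid == vol$scan_id, , drop = FALSE]
  n_pos <- round(n * cfg$positive_fraction)
  if (nrow(anns) == 0L && n_pos > 0L) {
    warning("no annotations for scan ", vol$scan_id,
            "; emitting negative patches only")
    n_pos <- 0L
  }
  centers_vox <- if (nrow(anns) > 0L)
    world_to_voxel(as.matrix(anns[, c("coordX", "coordY", "coordZ")]), vol)
  else matrix(numeric(0), 0, 3)

  bbox_lo <- c(0, 0, 0); bbox_hi <- vd - 1
  if (!is.null(lung_mask)) {
    idx <- which(lung_mask != 0, arr.ind = TRUE)
    if (nrow(idx) > 0L) { bbox_lo <- apply(idx, 2, min) - 1; bbox_hi <- apply(idx, 2, max) - 1 }
  }

  extract <- function(origin) {
    patch <- array(0, dim = rep(ps, 3))
    lo <- pmax(origin, 0); hi <- pmin(origin + ps - 1, vd - 1)
    if (all(lo <= hi)) {
      patch[(lo[1] - origin[1] + 1):(hi[1] - origin[1] + 1),
            (lo[2] - origin[2] + 1):(hi[2] - origin[2] + 1),
            (lo[3] - origin[3] + 1):(hi[3] - origin[3] + 1)] <-
        vol$voxels[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                   (lo[3] + 1):(hi[3] + 1)]
    }
    patch
  }

  local_annotations <- function(origin) {
    if (nrow(anns) == 0L)
      return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                        diameter = numeric(0)))
    local <- sweep(centers_vox, 2, origin, "-")
    inside <- apply(local, 1, function(p) all(p >= 0 & p <= ps - 1))
    diam_vox <- anns$diameter_mm / mean(vol$spacing)
    data.frame(z = local[inside, 1], y = local[inside, 2], x = local[inside, 3],
               diameter = diam_vox[inside])
  }

  patches <- vector("list", n)
  for (i in seq_len(n)) {
    if (i <= n_pos) {
      j <- sample.int(nrow(anns), 1L)
      jitter <- sample.int(ps %/% 2, 3L, replace = TRUE) - 1L - ps %/% 4
      origin <- round(centers_vox[j, ]) - ps %/% 2 + jitter
      # keep the chosen nodule centre inside the patch
      origin <- pmin(pmax(origin, ceiling(centers_vox[j, ]) - ps + 1),
                     floor(centers_vox[j, ]))
      positive <- TRUE
    } else {
      origin <- floor(c(runif(1, bbox_lo[1], max(bbox_lo[1], bbox_hi[1] - ps + 1)),
                        runif(1, bbox_lo[2], max(bbox_lo[2], bbox_hi[2] - ps + 1)),
                        runif(1, bbox_lo[3], max(bbox_lo[3], bbox_hi[3] - ps + 1))))
      positive <- FALSE
    }
    origin <- as.numeric(origin)
    patches[[i]] <- list(voxels = extract(origin), origin_voxel = origin,
                         annotations = local_annotations(origin),
                         positive = positive)
  }
  patches
}
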