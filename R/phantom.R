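#' Phantom generator configuration
#'
#' Describes a synthetic chest-CT phantom: an elliptical body at soft-tissue
#' density containing two air-filled lung ellipsoids, seeded with spherical
#' nodules. Nodule diameters follow a truncated log-normal (right-skewed, as
#' screening cohorts are); each nodule has a solid core occupying a sampled
#' fraction of its volume, surrounded by a ground-glass rim, so the cohort
#' spans the ground-glass-to-solid spectrum in the three conventional
#' strata 0-10%, 10-50% and 50-100% solid.
#'
#' @param volume_shape voxels `(z, y, x)`.
#' @param spacing mm per axis `(z, y, x)`.
#' @param n_nodules nodules per phantom.
#' @param diameter_median,diameter_sigma log-normal parameters of the nodule
#'   diameter in mm (median and log-sd), truncated to `diameter_range`.
#' @param diameter_range truncation bounds in mm.
#' @param solid_fraction_weights mixture weights over the solid-component
#'   bands 0-10%, 10-50% and 50-100%; must sum to 1. The fraction is uniform
#'   within the chosen band.
#' @param hu_lung,hu_body,hu_solid,hu_ggo tissue radiodensities (HU): lung
#'   parenchyma, chest wall / soft tissue, solid nodule core, ground-glass
#'   rim.
#' @param noise_sd additive Gaussian noise, HU.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(80L, 96L, 96L),
                           spacing = c(1, 1, 1),
                           n_nodules = 3L,
                           diameter_median = 8, diameter_sigma = 0.45,
                           diameter_range = c(4, 40),
                           solid_fraction_weights = c(0.3, 0.4, 0.3),
                           hu_lung = -850, hu_body = 40,
                           hu_solid = 40, hu_ggo = -600,
                           noise_sd = 20, seed = 1L) {
  if (n_nodules < 0) stop("n_nodules must be >= 0")
  if (abs(sum(solid_fraction_weights) - 1) > 1e-8)
    stop("solid_fraction_weights must sum to 1")
  if (diameter_range[1] <= 0 || diameter_range[2] <= diameter_range[1])
    stop("diameter_range must be increasing and positive")
  if (diameter_range[2] > min(volume_shape * spacing) / 2)
    stop("diameter_range exceeds half the volume extent")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 n_nodules = as.integer(n_nodules),
                 diameter_median = diameter_median,
                 diameter_sigma = diameter_sigma,
                 diameter_range = diameter_range,
                 solid_fraction_weights = solid_fraction_weights,
                 hu_lung = hu_lung, hu_body = hu_body,
                 hu_solid = hu_solid, hu_ggo = hu_ggo,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

sample_diameter <- function(cfg) {
  repeat {
    d <- rlnorm(1, meanlog = log(cfg$diameter_median), sdlog = cfg$diameter_sigma)
    if (d >= cfg$diameter_range[1] && d <= cfg$diameter_range[2]) return(d)
  }
}

sample_solid_fraction <- function(cfg) {
  band <- sample.int(3L, 1L, prob = cfg$solid_fraction_weights)
  lo <- c(0, 0.1, 0.5)[band]; hi <- c(0.1, 0.5, 1)[band]
  runif(1, lo, hi)
}

# voxel-centre coordinate grids (0-based), (z,y,x)
coord_grids <- function(shape) {
  list(z = array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]), dim = shape),
       x = array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), dim = shape))
}

in_ellipsoid <- function(g, centre, semi) {
  ((g$z - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$x - centre[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic chest-CT phantom
#'
#' Builds the body and lung geometry, places non-overlapping spherical
#' nodules whose centres (and full spheres) lie inside the lungs, rasterises
#' each as a ground-glass sphere with a centred solid core whose volume is
#' `solid_fraction` of the nodule volume (core radius
#' `r * solid_fraction^(1/3)`), adds Gaussian noise, and clips to
#' `[-1200, 600]` HU so downstream windowing never saturates unexpectedly.
#' Voxel values are rounded to single precision so MetaImage float round
#' trips are exact.
#'
#' @param cfg a [phantom_config()].
#' @param scan_id scan identifier for the volume and its annotations.
#' @return A `phantom`: list with `volume` (a [ct_volume()]), `lung_mask`
#'   (binary array, same grid), and `annotations` (LUNA16-dialect data frame
#'   with an extra `solid_fraction` column).
#' @export
generate_phantom <- function(cfg = phantom_config(), scan_id = "phantom") {
  set.seed(cfg$seed)
  shape <- cfg$volume_shape
  g <- coord_grids(shape)
  centre <- (shape - 1) / 2

  vol <- array(-1000, dim = shape)                       # background air
  body_semi <- (shape - 1) * c(0.48, 0.46, 0.46)
  body <- in_ellipsoid(g, centre, body_semi)
  vol[body] <- cfg$hu_body

  lung_semi <- (shape - 1) * c(0.38, 0.33, 0.20)
  offset_x <- (shape[3] - 1) * 0.22
  lungL <- in_ellipsoid(g, centre + c(0, 0, -offset_x), lung_semi)
  lungR <- in_ellipsoid(g, centre + c(0, 0, offset_x), lung_semi)
  lung_mask <- array(lungL | lungR, dim = shape)
  vol[lung_mask] <- cfg$hu_lung

  # nodule placement: full sphere inside a lung, pairwise non-overlapping
  anns <- data.frame(seriesuid = character(0), coordX = numeric(0),
                     coordY = numeric(0), coordZ = numeric(0),
                     diameter_mm = numeric(0), solid_fraction = numeric(0))
  placed <- matrix(numeric(0), 0, 4)                     # z, y, x, radius_vox
  for (i in seq_len(cfg$n_nodules)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      d_mm <- sample_diameter(cfg)
      r_vox <- d_mm / (2 * mean(cfg$spacing))
      side <- sample(c(-1, 1), 1)
      lc <- centre + c(0, 0, side * offset_x)
      if (any(lung_semi - r_vox - 1 <= 0)) next   # nodule too large for the lung
      u <- runif(3, -1, 1)
      cand <- lc + u * (lung_semi - r_vox - 1)
      # sphere fully inside the lung ellipsoid (conservative radial check)
      radial <- sqrt(sum(((cand - lc) / (lung_semi - r_vox - 1))^2))
      if (!is.finite(radial) || radial > 1) next
      if (nrow(placed) > 0) {
        dist <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cand)^2))
        if (any(dist < placed[, 4] + r_vox + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place nodule ", i, " without overlap; ",
                  "reduce n_nodules or the diameter range")
    sf <- sample_solid_fraction(cfg)
    dz <- g$z - cand[1]; dy <- g$y - cand[2]; dx <- g$x - cand[3]
    rr <- dz * dz + dy * dy + dx * dx
    vol[rr <= r_vox^2] <- cfg$hu_ggo
    core_r <- r_vox * sf^(1 / 3)
    vol[rr <= core_r^2] <- cfg$hu_solid
    placed <- rbind(placed, c(cand, r_vox))
    world <- c(rev(cand * cfg$spacing))                  # origin 0: (x,y,z) mm
    anns <- rbind(anns, data.frame(seriesuid = scan_id, coordX = world[1],
                                   coordY = world[2], coordZ = world[3],
                                   diameter_mm = d_mm, solid_fraction = sf))
  }

  vol <- vol + rnorm(length(vol), sd = cfg$noise_sd)
  vol[vol < -1200] <- -1200
  vol[vol > 600] <- 600
  structure(list(volume = ct_volume(as_single(vol), cfg$spacing, c(0, 0, 0), scan_id),
                 lung_mask = lung_mask, annotations = anns),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s'> %s voxels, %d nodule(s)\n", x$volume$scan_id,
              paste(dim(x$volume$voxels), collapse = "x"), nrow(x$annotations)))
  invisible(x)
}

#' Write or read nodule annotations (LUNA16 CSV dialect)
#'
#' Header `seriesuid,coordX,coordY,coordZ,diameter_mm`, one row per nodule,
#' world-mm coordinates; an optional `solid_fraction` column is preserved
#' when present.
#'
#' @param annotations data frame of annotations.
#' @param path CSV file path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns the data frame.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")
  if ("solid_fraction" %in% names(annotations)) cols <- c(cols, "solid_fraction")
  write.csv(annotations[, cols, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a phantom cohort
#'
#' Independent phantoms with per-scan seeds derived from a master seed, so
#' a cohort is reproducible as a whole and any scan individually.
#'
#' @param cfg a [phantom_config()]; its `seed` field is overridden per scan.
#' @param n_scans number of phantoms.
#' @param seed master seed.
#' @param prefix scan-id prefix.
#' @return List of `phantom` objects.
#' @export
generate_cohort <- function(cfg = phantom_config(), n_scans = 10L, seed = 1L,
                            prefix = "phantom") {
  stopifnot(n_scans >= 1)
  lapply(seq_len(n_scans), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((seed * 10007L + i) %% .Machine$integer.max)
    generate_phantom(cfg_i, scan_id = sprintf("%s_%03d", prefix, i))
  })
}

#' Combine cohort annotations into one data frame
#' @param cohort list of `phantom` objects.
#' @return Data frame of all annotations.
#' @export
cohort_annotations <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "annotations"))
}
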