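#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid in Hounsfield units together with its
#' voxel spacing and world origin. Axes are ordered `(z, y, x)` internally;
#' world coordinates are `(x, y, z)` millimetres, matching the convention of
#' the LUNA16 annotation files. Voxel indices are 0-based and refer to voxel
#' centres, so `world = origin + index * spacing` per axis.
#'
#' @param voxels 3D numeric array, axis order `(z, y, x)`.
#' @param spacing numeric length-3, mm per voxel along `(z, y, x)`; all > 0.
#' @param origin numeric length-3, world mm of voxel `(0,0,0)` in `(x, y, z)`
#'   order.
#' @param scan_id character scalar identifying the scan.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      scan_id = "scan") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must have exactly 3 axes, got ", length(dim(voxels)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (z, y, x)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must be length 3 (x, y, z) mm")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 scan_id = as.character(scan_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume '%s'> %s voxels (z,y,x), spacing %s mm, origin (%s) mm\n",
              x$scan_id, paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 6), collapse = ", ")))
  invisible(x)
}

#' Convert between world and voxel coordinates
#'
#' `world_to_voxel()` maps world-mm points `(x, y, z)` to continuous 0-based
#' voxel coordinates `(z, y, x)`; `voxel_to_world()` is its exact inverse.
#' Out-of-bounds results are returned as-is: bounds checking is the caller's
#' responsibility.
#'
#' @param p numeric length-3 or n-by-3 matrix of world points `(x, y, z)` mm.
#' @param vol a `ct_volume` (or any list with `spacing` and `origin`).
#' @return Matrix with one row per point: voxel coordinates `(z, y, x)` for
#'   `world_to_voxel()`, world coordinates `(x, y, z)` for `voxel_to_world()`.
#' @export
world_to_voxel <- function(p, vol) {
  p <- rbind_points(p)
  # world is (x,y,z); spacing stored (z,y,x)
  sp_xyz <- rev(vol$spacing)
  v_xyz <- sweep(sweep(p, 2, vol$origin, "-"), 2, sp_xyz, "/")
  v_xyz[, 3:1, drop = FALSE]
}

#' @rdname world_to_voxel
#' @param v numeric length-3 or n-by-3 matrix of voxel coordinates `(z, y, x)`.
#' @export
voxel_to_world <- function(v, vol) {
  v <- rbind_points(v)
  v_xyz <- v[, 3:1, drop = FALSE]
  sweep(sweep(v_xyz, 2, rev(vol$spacing), "*"), 2, vol$origin, "+")
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  if (ncol(p) != 3L) stop("points must have 3 columns")
  p
}

# ---- MetaImage (.mhd/.raw) ----

mhd_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_FLOAT = "double",
               MET_DOUBLE = "double")
mhd_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_mhd <- function(path, scan_id) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], "\\s*=\\s*")
  hdr <- setNames(vapply(kv, function(x) paste(x[-1], collapse = " "), ""),
                  vapply(kv, `[[`, "", 1))
  need <- function(key) {
    if (is.na(hdr[key])) stop("MetaImage header missing required field ", key)
    hdr[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L) stop("expected a 3D image, header declares NDims = ", ndims)
  dim_xyz <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing_xyz <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin_xyz <- if (!is.na(hdr["Offset"]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- need("ElementType")
  if (is.na(mhd_types[type])) stop("unsupported MetaImage ElementType ", type)
  if (!is.na(hdr["ElementByteOrderMSB"]) &&
      toupper(hdr[["ElementByteOrderMSB"]]) == "TRUE")
    stop("big-endian MetaImage data is not supported")
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop("MetaImage with LOCAL (single-file) data is not supported")
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path))
    stop("MetaImage data file not found: ", raw_path)
  n <- prod(dim_xyz)
  vals <- readBin(raw_path, what = mhd_types[[type]], n = n,
                  size = mhd_sizes[[type]], signed = !(type %in% c("MET_UCHAR", "MET_USHORT")),
                  endian = "little")
  if (length(vals) < n)
    stop("MetaImage data file shorter than DimSize implies: ", raw_path)
  arr <- array(as.double(vals), dim = dim_xyz)   # (x, y, z), x fastest
  ct_volume(aperm(arr, 3:1), spacing = rev(spacing_xyz), origin = origin_xyz,
            scan_id = scan_id)
}

write_mhd <- function(vol, path, element_type = "MET_FLOAT") {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  dim_xyz <- rev(dim(vol$voxels))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim_xyz, collapse = " ")),
           paste("ElementSpacing =", paste(format(rev(vol$spacing), trim = TRUE), collapse = " ")),
           paste("Offset =", paste(format(vol$origin, trim = TRUE), collapse = " ")),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  vals <- as.vector(aperm(vol$voxels, 3:1))
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (element_type == "MET_FLOAT") {
    writeBin(vals, con, size = 4L, endian = "little")
  } else if (element_type == "MET_SHORT") {
    writeBin(as.integer(round(vals)), con, size = 2L, endian = "little")
  } else if (element_type == "MET_DOUBLE") {
    writeBin(vals, con, size = 8L, endian = "little")
  } else stop("unsupported ElementType for writing: ", element_type)
  invisible(path)
}

# ---- NIfTI via RNifti ----

read_nifti_volume <- function(path, scan_id) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions")
  sp_xyz <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp_xyz)) || any(sp_xyz <= 0))
    stop("NIfTI image has missing or non-positive voxel spacing")
  xf <- RNifti::xform(img)
  origin_xyz <- xf[1:3, 4]
  ct_volume(aperm(arr, 3:1), spacing = rev(sp_xyz), origin = origin_xyz,
            scan_id = scan_id)
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$voxels, 3:1)
  img <- RNifti::asNifti(arr)
  sp_xyz <- rev(vol$spacing)
  RNifti::pixdim(img) <- sp_xyz
  m <- diag(c(sp_xyz, 1))
  m[1:3, 4] <- vol$origin
  attr(m, "code") <- 2L
  RNifti::`qform<-`(img, m) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write a CT volume
#'
#' Supports MetaImage (`.mhd` with a companion `.raw`) and NIfTI
#' (`.nii`/`.nii.gz`). MetaImage stores data x-fastest with `(x, y, z)`
#' header fields; both are converted to the package's `(z, y, x)` axis
#' order on read and back on write. Round trips are voxel-exact when
#' writing floating-point element types.
#'
#' @param path file path; the format is chosen by extension.
#' @param scan_id scan identifier; defaults to the file stem.
#' @return `read_volume()` returns a [ct_volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, scan_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(scan_id))
    scan_id <- sub("\\.(mhd|nii|nii\\.gz)$", "", basename(path))
  if (grepl("\\.mhd$", path)) read_mhd(path, scan_id)
  else if (grepl("\\.nii(\\.gz)?$", path)) read_nifti_volume(path, scan_id)
  else stop("unrecognised volume format (expected .mhd, .nii or .nii.gz): ", path)
}

#' @rdname read_volume
#' @param vol a [ct_volume()] (or normalized volume) to write.
#' @param element_type MetaImage element type for on-disk storage
#'   (`MET_FLOAT`, `MET_SHORT` or `MET_DOUBLE`); ignored for NIfTI.
#' @export
write_volume <- function(vol, path, element_type = "MET_FLOAT") {
  if (grepl("\\.mhd$", path)) write_mhd(vol, path, element_type)
  else if (grepl("\\.nii(\\.gz)?$", path)) write_nifti_volume(vol, path)
  else stop("unrecognised volume format (expected .mhd, .nii or .nii.gz): ", path)
}
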