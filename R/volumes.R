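#' Voxel-grid geometry shared by all volumes in an analysis
#'
#' All metrics in this package are grid-local: masks, count maps and 4-D
#' series are assumed co-registered onto one voxel grid, and world
#' coordinates are never needed. A `volume_grid` records the voxel counts,
#' the voxel size in mm and the voxel-to-world affine so that volumes can be
#' written back out as valid NIfTI-1.
#'
#' @param dims integer triple of voxel counts along i, j, k.
#' @param voxel_size mm triple, strictly positive. Default 1 mm isotropic.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by `voxel_size`.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be three strictly positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be an invertible 4x4 matrix")
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims)
}

n_voxels <- function(grid) prod(grid$dims)

#' Region-of-interest mask on a voxel grid
#'
#' A labelled binary occupancy volume for one cortical area or subcortical
#' structure in one hemisphere. Occupancy is stored as the sorted linear
#' indices of occupied voxels (0-based lexicographic, i fastest), which is
#' compact and makes voxel order deterministic.
#'
#' @param grid a [volume_grid()].
#' @param voxels 0-based linear voxel indices of the occupied voxels, or a
#'   logical/numeric array of dimensions `grid$dims`.
#' @param label ROI label, e.g. one of the 17 cortical area abbreviations or
#'   "STN"/"STR".
#' @param hemisphere "L" or "R".
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(grid, voxels, label, hemisphere) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.array(voxels) || (is.logical(voxels) && length(voxels) == n_voxels(grid))) {
    if (is.array(voxels) && !identical(dim(voxels), as.integer(grid$dims)))
      stop("occupancy array dimensions do not match the grid")
    occ <- as.vector(voxels)
    if (!all(occ %in% c(0, 1, TRUE, FALSE)))
      stop("occupancy must be strictly binary")
    voxels <- which(as.logical(occ)) - 1L
  } else {
    voxels <- sort(unique(as.integer(voxels)))
    if (any(voxels < 0L) || any(voxels >= n_voxels(grid)))
      stop("voxel indices out of range for the grid")
  }
  if (length(voxels) == 0L) stop("an ROI mask must occupy at least one voxel")
  if (!hemisphere %in% c("L", "R")) stop("hemisphere must be 'L' or 'R'")
  structure(list(grid = grid, voxels = as.integer(voxels),
                 label = as.character(label), hemisphere = hemisphere),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s (%s): %d voxels\n", x$label, x$hemisphere,
              length(x$voxels)))
  invisible(x)
}

#' Number of occupied voxels in a mask
#' @param mask an [roi_mask()].
#' @export
mask_size <- function(mask) length(mask$voxels)

mask_array <- function(mask) {
  a <- array(0, dim = mask$grid$dims)
  a[mask$voxels + 1L] <- 1
  a
}

#' Per-seed-voxel streamline sample counts for one directed tract
#'
#' The output of probabilistic tractography for one seed -> target pair:
#' for each voxel of the seed mask, the number of the `n_samples` streamline
#' samples launched from it that reached the target mask. Stored sparsely as
#' values over the seed-mask voxels (all other voxels are implicitly zero).
#'
#' @param seed_mask the [roi_mask()] the tract was seeded in.
#' @param values nonnegative counts, one per seed-mask voxel (in the mask's
#'   sorted voxel order).
#' @param n_samples samples launched per voxel (study value 5000).
#' @param target_label label of the target ROI.
#' @param distance_corrected logical; `FALSE` for raw integer counts. When
#'   `FALSE`, values must be integers in `[0, n_samples]`.
#' @return an object of class `sample_count_map`.
#' @export
sample_count_map <- function(seed_mask, values, n_samples, target_label,
                             distance_corrected = FALSE) {
  stopifnot(inherits(seed_mask, "roi_mask"))
  values <- as.numeric(values)
  if (length(values) != mask_size(seed_mask))
    stop("need one value per seed-mask voxel")
  if (any(!is.finite(values)) || any(values < 0))
    stop("sample counts must be finite and nonnegative")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples <= 0L) stop("'n_samples' must be positive")
  if (!distance_corrected) {
    if (any(values != round(values)) || any(values > n_samples))
      stop("uncorrected counts must be integers <= n_samples")
  }
  structure(list(grid = seed_mask$grid, seed_voxels = seed_mask$voxels,
                 values = values, n_samples = n_samples,
                 seed_label = seed_mask$label, target_label = target_label,
                 hemisphere = seed_mask$hemisphere,
                 distance_corrected = isTRUE(distance_corrected)),
            class = "sample_count_map")
}

#' @export
print.sample_count_map <- function(x, ...) {
  cat(sprintf("<sample_count_map> %s -> %s (%s): %d seed voxels, n_samples=%d%s\n",
              x$seed_label, x$target_label, x$hemisphere, length(x$seed_voxels),
              x$n_samples, if (x$distance_corrected) ", distance-corrected" else ""))
  invisible(x)
}

#' Densify a sparse count map into a full 3-D array
#' @param map a [sample_count_map()].
#' @return numeric array of the grid's dimensions, zero outside the seed mask.
#' @export
count_map_array <- function(map) {
  a <- array(0, dim = map$grid$dims)
  a[map$seed_voxels + 1L] <- map$values
  a
}

#' One ROI's mean BOLD time series
#'
#' @param samples ordered real sequence of length T >= 2, all finite.
#' @param label,hemisphere ROI identity.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(samples, label, hemisphere) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("a time series needs at least 2 timepoints")
  if (any(!is.finite(samples))) stop("time series values must be finite")
  structure(list(samples = samples, label = as.character(label),
                 hemisphere = hemisphere),
            class = "roi_timeseries")
}

# ---- NIfTI IO ---------------------------------------------------------------

grid_from_nifti <- function(img) {
  d <- dim(img)
  voxdim <- RNifti::pixdim(img)
  volume_grid(d[1:3], voxdim[1:3], affine = unclass(RNifti::xform(img)))
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D or 4-D NIfTI-1 file and returns the voxel grid plus the value
#' array. Integer data round-trip bit-exactly through [write_volume()].
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `grid` (a [volume_grid()]) and `values`
#'   (a 3-D or 4-D array; time is the last axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("failed to parse NIfTI file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  nd <- length(dim(img))
  if (nd < 3L || nd > 4L)
    stop("expected a 3-D or 4-D NIfTI payload, got ", nd, " dimensions")
  list(grid = grid_from_nifti(img), values = array(as.numeric(img), dim = dim(img)))
}

#' Write a volume as NIfTI-1
#'
#' @param values 3-D or 4-D array (time last).
#' @param grid the [volume_grid()] giving voxel size and affine.
#' @param path destination `.nii` or `.nii.gz` path.
#' @param datatype NIfTI storage type; `"int32"` preserves counts exactly,
#'   `"double"` preserves floats to machine precision.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path, datatype = "double") {
  stopifnot(inherits(grid, "volume_grid"))
  d <- dim(values)
  if (is.null(d) || length(d) < 3L || !identical(as.integer(d[1:3]), grid$dims))
    stop("value array does not match the grid dimensions")
  img <- RNifti::asNifti(values, reference = NULL)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::pixdim(img) <- c(grid$voxel_size, rep(1, length(d) - 3L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Restrict a value array to a mask
#'
#' Returns the values at exactly the occupied voxels of the mask, in
#' deterministic lexicographic voxel order (0-based, i fastest).
#'
#' @param values 3-D array on the mask's grid.
#' @param mask an [roi_mask()].
#' @return data.frame with columns `voxel` (0-based linear index) and `value`.
#' @export
restrict_to_mask <- function(values, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  d <- dim(values)
  if (is.null(d) || !identical(as.integer(d), mask$grid$dims))
    stop("value array dimensions do not match the mask's grid")
  data.frame(voxel = mask$voxels, value = as.vector(values)[mask$voxels + 1L])
}

# ---- sidecar table ----------------------------------------------------------

#' Read the mask/map sidecar table
#'
#' ROI identity is never parsed from filenames; a sidecar CSV with columns
#' `filename,label,hemisphere,role` accompanies every volume directory.
#' `role` is one of `mask`, `count_map_fwd`, `count_map_rev`, `bold`.
#'
#' @param path path to the sidecar CSV.
#' @return data.frame with the four columns, validated.
#' @export
read_sidecar <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "label", "hemisphere", "role")
  if (!all(need %in% names(tab)))
    stop("sidecar table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$role), c("mask", "count_map_fwd", "count_map_rev", "bold"))
  if (length(bad)) stop("unknown sidecar role(s): ", paste(bad, collapse = ", "))
  tab[need]
}
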