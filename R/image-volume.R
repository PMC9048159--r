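#' Image volume container
#'
#' A 3-D scalar image grid with world-coordinate geometry, the common currency
#' of every QA analysis in the package. The world frame is the DICOM patient
#' coordinate system (LPS), all distances in millimetres, with the scanner
#' isocentre at the world origin unless the series says otherwise. Voxel
#' indices are 0-based and refer to voxel centres.
#'
#' @param voxels 3-D numeric array; first index is x (columns), second y
#'   (rows), third z (slices).
#' @param spacing length-3 positive numeric, mm per voxel along x, y, z.
#' @param origin length-3 numeric, world position (mm) of the centre of voxel
#'   (0, 0, 0).
#' @param direction 3x3 orthonormal direction-cosine matrix; columns are the
#'   world directions of the x, y, z voxel axes.
#' @param modality "MR" or "PET".
#' @param units value units, e.g. "a.u." for MR or "Bq/ml" for PET. PET
#'   volumes must carry units.
#' @param acquisition_time acquisition timestamp (`POSIXct` or `NULL`).
#' @param meta named list of extra metadata (b-value `b_value` in s/mm2,
#'   series description, ...).
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         direction = diag(3), modality = c("MR", "PET"),
                         units = NULL, acquisition_time = NULL, meta = list()) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !length(voxels))
    abort_qa("voxels must be a non-empty 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort_qa("spacing must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort_qa("origin must be 3 finite numbers (mm)")
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(abs(det(direction)) - 1) > 1e-6)
    abort_qa("direction must be an orthonormal 3x3 matrix")
  if (modality == "PET" && is.null(units))
    abort_qa("PET volumes must carry units metadata (e.g. \"Bq/ml\")")
  if (is.null(units)) units <- "a.u."
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction, modality = modality, units = units,
                 acquisition_time = acquisition_time, meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("<image_volume> %s %dx%dx%d, spacing %.3gx%.3gx%.3g mm, units %s\n",
              x$modality, dm[1], dm[2], dm[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  if (!is.null(x$meta$b_value))
    cat(sprintf("  b-value: %g s/mm^2\n", x$meta$b_value))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' Map voxel indices to world coordinates
#'
#' Voxel indices are 0-based, fractional indices allowed, and refer to voxel
#' centres: `world = origin + direction %*% (spacing * index)`.
#'
#' @param volume an [image_volume()].
#' @param index numeric length-3 vector or n x 3 matrix of 0-based indices.
#' @return numeric length-3 vector or n x 3 matrix of world points (mm).
#' @export
voxel_to_world <- function(volume, index) {
  stopifnot(is_image_volume(volume))
  one <- is.null(dim(index))
  idx <- if (one) matrix(as.numeric(index), 1, 3) else as.matrix(index)
  w <- sweep(idx, 2, volume$spacing, `*`) %*% t(volume$direction)
  w <- sweep(w, 2, volume$origin, `+`)
  if (one) drop(w) else w
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#' @inheritParams voxel_to_world
#' @param world numeric length-3 vector or n x 3 matrix of world points (mm).
#' @return indices in voxel space (0-based, fractional).
#' @export
world_to_voxel <- function(volume, world) {
  stopifnot(is_image_volume(volume))
  one <- is.null(dim(world))
  w <- if (one) matrix(as.numeric(world), 1, 3) else as.matrix(world)
  w <- sweep(w, 2, volume$origin, `-`) %*% volume$direction  # t(D^-1) = D
  idx <- sweep(w, 2, volume$spacing, `/`)
  if (one) drop(idx) else idx
}

#' World coordinates of every voxel centre along each axis
#'
#' Convenience for axis-aligned volumes: returns the world coordinate of each
#' voxel centre along x, y and z. Only valid when `direction` is the identity.
#'
#' @param volume an [image_volume()].
#' @return list with numeric vectors `x`, `y`, `z` (mm).
#' @export
axis_coords <- function(volume) {
  stopifnot(is_image_volume(volume))
  if (max(abs(volume$direction - diag(3))) > 1e-9)
    abort_qa("axis_coords requires an axis-aligned (identity direction) volume")
  dm <- dim(volume$voxels)
  list(x = volume$origin[1] + volume$spacing[1] * (seq_len(dm[1]) - 1),
       y = volume$origin[2] + volume$spacing[2] * (seq_len(dm[2]) - 1),
       z = volume$origin[3] + volume$spacing[3] * (seq_len(dm[3]) - 1))
}

# origin such that the volume is centred on the world origin (isocentre)
centred_origin <- function(dm, spacing) -(dm - 1) / 2 * spacing

#' Export a volume to NIfTI-1 for external inspection
#'
#' Requires the suggested RNifti package. Geometry is carried over; note the
#' NIfTI world frame is RAS while this package works in LPS.
#'
#' @param volume an [image_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return the path, invisibly.
#' @export
export_nifti <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort_qa("export_nifti requires the RNifti package")
  img <- RNifti::asNifti(volume$voxels)
  # LPS -> RAS flips the first two axes
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(c(-1, -1, 1)) %*%
    (volume$direction %*% diag(volume$spacing))
  aff[1:3, 4] <- c(-1, -1, 1) * volume$origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
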