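# PET-MR alignment: detect the five PET spheres and ten MR spheres, pair
# the MR spheres superior/inferior, take pair midpoints (which coincide
# with the PET sphere centres in a perfectly aligned scanner), and recover
# the residual six-degrees-of-freedom misalignment by rigid registration of
# the MR midpoints onto the PET centroids.

#' Detect a known number of spheres in a volume
#'
#' Top-k bright-blob detection with sub-voxel intensity-weighted centroids.
#' Candidates within half the brightest blob's intensity count as spheres;
#' any other count than `expected_count` is an error.
#'
#' @param volume an [image_volume()].
#' @param expected_count number of spheres that must be present.
#' @param radius_mm nominal sphere radius, mm.
#' @return data.frame (`sphere_detections`) `x`, `y`, `z`, `intensity`,
#'   `radius_est` with attribute `modality`.
#' @export
detect_spheres <- function(volume, expected_count, radius_mm = 6) {
  blobs <- detect_blobs(volume, radius_mm = radius_mm, threshold_frac = 0.25,
                        min_separation_mm = 2 * radius_mm)
  keep <- blobs$intensity >= 0.5 * max(blobs$intensity)
  found <- blobs[keep, , drop = FALSE]
  if (nrow(found) != expected_count)
    abort_qa(sprintf(
      "expected %d spheres, found %d; candidates at intensities %s",
      expected_count, nrow(found),
      paste(sprintf("%.3g", blobs$intensity), collapse = ", ")))
  attr(found, "modality") <- volume$modality
  class(found) <- c("sphere_detections", "data.frame")
  found
}

#' Midpoints of superior/inferior MR sphere pairs
#'
#' Pairs the ten MR sphere centroids by mutual nearest neighbour, requiring
#' each pair to be separated predominantly along SI and by no more than
#' `max_pair_sep_mm`; the midpoint of each pair is the arithmetic mean of
#' the two centroids.
#'
#' @param mr a `sphere_detections` of 10 MR spheres.
#' @param max_pair_sep_mm maximum allowed intra-pair separation, mm.
#' @return 5 x 3 matrix of midpoints (mm).
#' @export
mr_pair_midpoints <- function(mr, max_pair_sep_mm = 40) {
  pts <- as.matrix(mr[, c("x", "y", "z")])
  n <- nrow(pts)
  if (n != 10L) abort_qa("MR sphere pairing needs exactly 10 detections")
  d2 <- outer(rowSums(pts^2), rowSums(pts^2), `+`) - 2 * pts %*% t(pts)
  diag(d2) <- Inf
  nn <- max.col(-d2)
  used <- logical(n)
  mids <- NULL
  for (i in seq_len(n)) {
    if (used[i]) next
    j <- nn[i]
    if (nn[j] != i)
      abort_qa(sprintf("ambiguous MR sphere pairing near (%0.1f, %0.1f, %0.1f)",
                       pts[i, 1], pts[i, 2], pts[i, 3]))
    if (used[j]) abort_qa("MR sphere pairing conflict")
    sep <- pts[j, ] - pts[i, ]
    if (sqrt(sum(sep^2)) > max_pair_sep_mm)
      abort_qa("MR sphere pair separation exceeds the pairing window")
    if (abs(sep[3]) <= sqrt(sep[1]^2 + sep[2]^2))
      abort_qa("MR sphere pair is not separated along SI; pairing rejected")
    used[i] <- used[j] <- TRUE
    mids <- rbind(mids, (pts[i, ] + pts[j, ]) / 2)
  }
  if (nrow(mids) != 5L) abort_qa("did not form 5 MR sphere pairs")
  mids
}

#' Register MR pair midpoints onto PET sphere centroids
#'
#' Establishes midpoint-to-centroid correspondence by nearest neighbour
#' (misalignments are small compared with the sphere grid pitch), then
#' computes the closed-form least-squares rigid transform ([kabsch_fit()])
#' mapping MR midpoints onto PET centroids. The reported transform direction
#' is MR -> PET.
#'
#' @param mr_midpoints 5 x 3 matrix from [mr_pair_midpoints()].
#' @param pet_centroids `sphere_detections` of the 5 PET spheres, or a
#'   5 x 3 matrix.
#' @return object of class `alignment_result`: list with `transform`
#'   (a [rigid_transform()]; translations are the RL/AP/SI differences) and
#'   `residual_rms` (mm).
#' @export
register_alignment <- function(mr_midpoints, pet_centroids) {
  pet <- if (is.data.frame(pet_centroids))
    as.matrix(pet_centroids[, c("x", "y", "z")]) else as.matrix(pet_centroids)
  mr <- as.matrix(mr_midpoints)
  if (nrow(mr) != nrow(pet) || nrow(mr) < 3L)
    abort_qa("need equal point counts (>= 3) to register")
  d2 <- outer(rowSums(mr^2), rowSums(pet^2), `+`) - 2 * mr %*% t(pet)
  ord <- max.col(-d2)
  if (anyDuplicated(ord))
    abort_qa("could not establish one-to-one midpoint/centroid correspondence")
  fit <- kabsch_fit(mr, pet[ord, , drop = FALSE])
  structure(list(transform = fit$transform, residual_rms = fit$residual_rms),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("PET-MR alignment (MR midpoints -> PET centroids):\n")
  print(x$transform)
  cat(sprintf("  residual RMS: %.4g mm\n", x$residual_rms))
  invisible(x)
}

#' Full PET-MR alignment pipeline
#'
#' Detects spheres on both modalities, pairs the MR spheres, and registers
#' the pair midpoints onto the PET centroids.
#'
#' @param mr,pet [image_volume()]s of the sphere phantom.
#' @param sphere_radius_mm nominal sphere radius, mm.
#' @param max_pair_sep_mm MR pairing window, mm.
#' @return an `alignment_result`.
#' @export
analyze_alignment <- function(mr, pet, sphere_radius_mm = 6,
                              max_pair_sep_mm = 40) {
  mr_det <- detect_spheres(mr, 10L, radius_mm = sphere_radius_mm)
  pet_det <- detect_spheres(pet, 5L, radius_mm = sphere_radius_mm)
  mids <- mr_pair_midpoints(mr_det, max_pair_sep_mm = max_pair_sep_mm)
  register_alignment(mids, pet_det)
}
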