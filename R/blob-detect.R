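# Bright-blob detection with sub-voxel centroids.
#
# Markers and spheres are near-Gaussian bright blobs on a dark background.
# Detection: candidate voxels above an intensity threshold that are 26-
# neighbourhood local maxima; each maximum is refined to a sub-voxel centre
# by a background-subtracted intensity-weighted centroid over a window of
# +-1.5 blob radii (3 sigma for a Gaussian of sigma = radius/2, keeping the
# truncation bias of the centroid below 0.02 mm).

#' Detect bright blobs and return sub-voxel world centroids
#'
#' @param volume an [image_volume()].
#' @param radius_mm nominal blob radius (mm); sets the centroid window.
#' @param threshold absolute intensity threshold for candidate voxels;
#'   default background + `threshold_frac` of the background-to-peak range.
#' @param threshold_frac fraction used for the default threshold.
#' @param min_separation_mm maxima closer than this are merged keeping the
#'   brighter one; defaults to `radius_mm`.
#' @param max_blobs optional cap: keep the brightest `max_blobs` detections.
#' @return data.frame with columns `x`, `y`, `z` (world mm), `intensity`
#'   (peak value) and `radius_est` (intensity-weighted RMS radius, mm).
#' @export
detect_blobs <- function(volume, radius_mm, threshold = NULL,
                         threshold_frac = 0.25, min_separation_mm = NULL,
                         max_blobs = NULL) {
  stopifnot(is_image_volume(volume))
  arr <- volume$voxels
  dm <- dim(arr)
  bg <- stats::median(arr)
  if (is.null(threshold)) threshold <- bg + threshold_frac * (max(arr) - bg)
  if (is.null(min_separation_mm)) min_separation_mm <- radius_mm

  cand <- which(arr > threshold)
  if (!length(cand))
    abort_qa("detect_blobs: no voxels above threshold")
  i0 <- cand - 1L
  nx <- dm[1]; ny <- dm[2]
  ix <- i0 %% nx
  iy <- (i0 %/% nx) %% ny
  iz <- i0 %/% (nx * ny)
  interior <- ix > 0L & ix < nx - 1L & iy > 0L & iy < ny - 1L &
    iz > 0L & iz < dm[3] - 1L
  cand <- cand[interior]
  if (!length(cand)) abort_qa("detect_blobs: all candidates on the border")
  v <- arr[cand]
  is_max <- rep(TRUE, length(cand))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    off <- dx + dy * nx + dz * nx * ny
    is_max <- is_max & v >= arr[cand + off]
  }
  peaks <- cand[is_max]
  if (!length(peaks)) abort_qa("detect_blobs: no local maxima found")
  pv <- arr[peaks]

  # merge plateau/nearby maxima: greedy by brightness
  p0 <- peaks - 1L
  pix <- p0 %% nx; piy <- (p0 %/% nx) %% ny; piz <- p0 %/% (nx * ny)
  pw <- cbind(pix, piy, piz)
  ord <- order(pv, decreasing = TRUE)
  keep <- logical(length(peaks))
  sep_vox <- min_separation_mm / volume$spacing
  taken <- matrix(numeric(0), 0, 3)
  for (j in ord) {
    p <- pw[j, ]
    if (nrow(taken)) {
      d <- sweep(taken, 2, p)
      if (any(rowSums(sweep(d, 2, sep_vox, `/`)^2) < 1)) next
    }
    keep[j] <- TRUE
    taken <- rbind(taken, p)
    if (!is.null(max_blobs) && nrow(taken) >= max_blobs) break
  }
  peaks <- peaks[keep]; pw <- pw[keep, , drop = FALSE]; pv <- arr[peaks]

  # sub-voxel centroid per peak
  h <- pmax(2L, as.integer(ceiling(1.5 * radius_mm / volume$spacing)))
  res <- matrix(NA_real_, nrow(pw), 5)
  for (j in seq_len(nrow(pw))) {
    c0 <- pw[j, ]
    lo <- pmax(c0 - h, 0L); hi <- pmin(c0 + h, dm - 1L)
    xs <- (lo[1]:hi[1]); ys <- (lo[2]:hi[2]); zs <- (lo[3]:hi[3])
    w <- arr[xs + 1L, ys + 1L, zs + 1L, drop = FALSE]
    # local background: median of window faces
    face <- c(w[1, , ], w[length(xs), , ], w[, 1, ], w[, length(ys), ],
              w[, , 1], w[, , length(zs)])
    wb <- pmax(w - stats::median(face), 0)
    s <- sum(wb)
    if (s <= 0) next
    gx <- sum(slice.index(wb, 1) * wb) / s
    gy <- sum(slice.index(wb, 2) * wb) / s
    gz <- sum(slice.index(wb, 3) * wb) / s
    ci <- c(xs[1] - 1 + gx, ys[1] - 1 + gy, zs[1] - 1 + gz)
    r2 <- sum(((slice.index(wb, 1) - gx) * volume$spacing[1])^2 * wb +
                ((slice.index(wb, 2) - gy) * volume$spacing[2])^2 * wb +
                ((slice.index(wb, 3) - gz) * volume$spacing[3])^2 * wb) / s
    res[j, ] <- c(ci, pv[j], sqrt(r2))
  }
  ok <- !is.na(res[, 1])
  res <- res[ok, , drop = FALSE]
  wpts <- voxel_to_world(volume, res[, 1:3, drop = FALSE])
  out <- data.frame(x = wpts[, 1], y = wpts[, 2], z = wpts[, 3],
                    intensity = res[, 4], radius_est = res[, 5])
  out[order(-out$intensity), , drop = FALSE]
}
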