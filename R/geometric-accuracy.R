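# Large field-of-view MR geometric distortion analysis: detect the grid
# markers, remove the phantom setup error with a rigid fit on the central
# markers, report per-marker distortion shifts and concentric-shell means,
# and summarise repeatability/stability across sessions per marker.

#' Reference marker grid
#'
#' The known nominal marker layout of a distortion grid phantom, in the
#' phantom frame (assumed nominally aligned with the scanner frame, origin
#' at isocentre).
#'
#' @param nominal data.frame with columns `id`, `x`, `y`, `z` (mm); IDs unique.
#' @param grid_spacing lattice pitch, mm (used for matching gates).
#' @param marker_radius nominal marker radius, mm (detection window).
#' @return object of class `reference_grid`.
#' @export
reference_grid <- function(nominal, grid_spacing, marker_radius = 6) {
  stopifnot(is.data.frame(nominal),
            all(c("id", "x", "y", "z") %in% names(nominal)))
  if (anyDuplicated(nominal$id)) abort_qa("marker IDs must be unique")
  structure(list(nominal = nominal, grid_spacing = grid_spacing,
                 marker_radius = marker_radius),
            class = "reference_grid")
}

#' Reference grid matching a synthetic grid phantom spec
#' @param spec a [grid_phantom_spec()].
#' @return a [reference_grid()].
#' @export
reference_grid_from_spec <- function(spec) {
  reference_grid(grid_nominal_positions(spec), spec$grid_spacing,
                 spec$marker_radius)
}

#' Detect grid markers and assign nominal IDs
#'
#' Candidate blobs are found by thresholded local-maximum detection with
#' sub-voxel intensity-weighted centroids ([detect_blobs()]). A coarse rigid
#' setup alignment (two matching/fitting passes) maps candidates into the
#' nominal frame; each candidate is then assigned the nearest nominal ID
#' within half a grid pitch. When two candidates claim one ID the brighter
#' is kept and the other reported as spurious; nominal IDs with no candidate
#' are reported missing.
#'
#' @param volume an [image_volume()] of the grid phantom.
#' @param grid a [reference_grid()].
#' @param threshold_frac detection threshold as a fraction of the background
#'   to peak intensity range.
#' @return data.frame (`marker_set`) with `id`, `x`, `y`, `z` (world mm) and
#'   `intensity`; attributes `missing` (unmatched IDs) and `spurious`
#'   (data.frame of dropped candidates).
#' @export
detect_markers <- function(volume, grid, threshold_frac = 0.25) {
  stopifnot(inherits(grid, "reference_grid"))
  blobs <- detect_blobs(volume, radius_mm = grid$marker_radius,
                        threshold_frac = threshold_frac,
                        min_separation_mm = grid$grid_spacing / 3)
  nom <- as.matrix(grid$nominal[, c("x", "y", "z")])
  meas <- as.matrix(blobs[, c("x", "y", "z")])
  gate <- grid$grid_spacing / 2

  nearest_nominal <- function(pts) {
    # for each point, index + distance of nearest nominal marker
    d2 <- outer(rowSums(pts^2), rowSums(nom^2), `+`) - 2 * pts %*% t(nom)
    j <- max.col(-d2)
    list(j = j, d = sqrt(pmax(d2[cbind(seq_len(nrow(pts)), j)], 0)))
  }

  # coarse setup alignment: match, fit measured -> nominal, re-match
  m <- nearest_nominal(meas)
  ok <- m$d < gate
  aligned <- meas
  if (sum(ok) >= 3) {
    fit <- kabsch_fit(meas[ok, , drop = FALSE], nom[m$j[ok], , drop = FALSE])
    aligned <- apply_rigid(fit$transform, meas)
    m <- nearest_nominal(aligned)
  }

  keep <- m$d < gate
  assign_id <- rep(NA_integer_, nrow(meas))
  assign_id[keep] <- m$j[keep]
  spurious_idx <- integer(0)
  # resolve conflicts: keep the brighter candidate
  for (j in unique(assign_id[!is.na(assign_id)])) {
    cand <- which(!is.na(assign_id) & assign_id == j)
    if (length(cand) > 1L) {
      best <- cand[which.max(blobs$intensity[cand])]
      lose <- setdiff(cand, best)
      assign_id[lose] <- NA_integer_
      spurious_idx <- c(spurious_idx, lose)
    }
  }
  spurious_idx <- union(spurious_idx, which(is.na(assign_id)))
  matched <- which(!is.na(assign_id))
  if (length(matched) < 0.5 * nrow(nom))
    abort_qa(sprintf(
      "only %d of %d expected markers found; wrong phantom or series?",
      length(matched), nrow(nom)))

  out <- data.frame(id = grid$nominal$id[assign_id[matched]],
                    x = blobs$x[matched], y = blobs$y[matched],
                    z = blobs$z[matched],
                    intensity = blobs$intensity[matched])
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  attr(out, "missing") <- setdiff(grid$nominal$id, out$id)
  attr(out, "spurious") <- blobs[spurious_idx, , drop = FALSE]
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Per-marker distortion shifts and concentric-shell means
#'
#' The phantom setup error is removed by a six-degrees-of-freedom rigid fit
#' of nominal onto measured positions using only markers within
#' `setup_fit_radius_mm` of the isocentre (where true distortion is
#' smallest); the residual displacement of each marker is reported as
#' distortion. Shift is the absolute 3-D Euclidean distance between the
#' measured position and the setup-transformed nominal position. Markers are
#' binned by distance of the measured position from the isocentre
#' (lower-edge-inclusive shells).
#'
#' @param markers a `marker_set` from [detect_markers()].
#' @param grid a [reference_grid()].
#' @param shell_edges_mm inner shell boundaries, mm.
#' @param setup_fit_radius_mm radius used for the setup fit, mm.
#' @param sequence label carried into reports ("2D"/"3D").
#' @return object of class `distortion_result`: list with `per_marker`
#'   (id, measured position, `shift`, `dist_iso`, `shell`), `shell_means`,
#'   `setup_transform` and `sequence`.
#' @export
compute_distortion <- function(markers, grid,
                               shell_edges_mm = c(100, 150, 200, 250),
                               setup_fit_radius_mm = 100, sequence = "3D") {
  if (!nrow(markers)) abort_qa("empty marker set")
  nom <- grid$nominal
  idx <- match(markers$id, nom$id)
  if (anyNA(idx)) abort_qa("marker set contains IDs not in the reference grid")
  meas <- as.matrix(markers[, c("x", "y", "z")])
  nompts <- as.matrix(nom[idx, c("x", "y", "z")])

  dist_iso <- sqrt(rowSums(meas^2))
  inner <- dist_iso < setup_fit_radius_mm
  if (sum(inner) < 3) inner <- rep(TRUE, nrow(meas))
  fit <- kabsch_fit(nompts[inner, , drop = FALSE], meas[inner, , drop = FALSE])
  expected <- apply_rigid(fit$transform, nompts)
  shift <- sqrt(rowSums((meas - expected)^2))

  edges <- c(0, shell_edges_mm, Inf)
  labels <- shell_labels(shell_edges_mm)
  shell <- labels[findInterval(dist_iso, edges)]
  per_marker <- data.frame(id = markers$id, x = meas[, 1], y = meas[, 2],
                           z = meas[, 3], shift = shift, dist_iso = dist_iso,
                           shell = factor(shell, levels = labels))
  sm <- stats::aggregate(shift ~ shell, per_marker, mean, drop = FALSE)
  names(sm)[2] <- "mean_shift"
  sm$n <- as.integer(table(per_marker$shell)[as.character(sm$shell)])
  structure(list(per_marker = per_marker, shell_means = sm,
                 setup_transform = fit$transform, sequence = sequence),
            class = "distortion_result")
}

shell_labels <- function(edges_mm) {
  cm <- edges_mm / 10
  c(sprintf("d<%gcm", cm[1]),
    sprintf("%g<=d<%gcm", cm[-length(cm)], cm[-1]),
    sprintf("d>=%gcm", cm[length(cm)]))
}

#' Longitudinal per-marker distortion statistics
#'
#' Over a set of sessions (three same-day repeats, or twelve monthly
#' measurements), restricts to markers identified in every session, then
#' computes each marker's mean shift, sample standard deviation (n - 1
#' denominator) and range. The headline statistic is the arithmetic mean of
#' the per-marker SDs, together with the mean per-marker range. Markers not
#' common to all sessions are excluded and reported.
#'
#' @param sessions list of `distortion_result` objects (>= 2).
#' @return object of class `longitudinal_distortion`: list with `per_marker`
#'   (id, mean, sd, range), `mean_sd`, `mean_range`, `n_sessions`,
#'   `excluded` (data.frame id, n_present).
#' @export
longitudinal_stats <- function(sessions) {
  if (length(sessions) < 2L) abort_qa("need at least 2 sessions")
  ids_list <- lapply(sessions, function(s) s$per_marker$id)
  common <- Reduce(intersect, ids_list)
  if (!length(common)) abort_qa("no markers common to all sessions")
  all_ids <- unique(unlist(ids_list))
  excluded_ids <- setdiff(all_ids, common)
  excluded <- data.frame(
    id = excluded_ids,
    n_present = vapply(excluded_ids, function(i)
      sum(vapply(ids_list, function(v) i %in% v, logical(1))), integer(1)))
  shifts <- vapply(sessions, function(s)
    s$per_marker$shift[match(common, s$per_marker$id)], numeric(length(common)))
  shifts <- matrix(shifts, nrow = length(common))
  per_marker <- data.frame(
    id = common,
    mean = rowMeans(shifts),
    sd = apply(shifts, 1, stats::sd),
    range = apply(shifts, 1, function(v) max(v) - min(v)))
  structure(list(per_marker = per_marker,
                 mean_sd = mean(per_marker$sd),
                 mean_range = mean(per_marker$range),
                 n_sessions = length(sessions), excluded = excluded),
            class = "longitudinal_distortion")
}

#' Compare shell-mean distortion against the clinical tolerance
#'
#' Shells below 25 cm from the isocentre are compared against the 2.0 mm
#' distortion limit recommended for MR-only radiotherapy; the outermost
#' shell is reported without a tolerance.
#'
#' @param result a `distortion_result`.
#' @param limit_mm tolerance for shells inside `no_tolerance_from_mm`.
#' @param no_tolerance_from_mm distance beyond which no tolerance applies.
#' @return data.frame `shell`, `n`, `mean_shift`, `limit`, `verdict`.
#' @export
check_tolerance <- function(result, limit_mm = 2.0,
                            no_tolerance_from_mm = 250) {
  stopifnot(inherits(result, "distortion_result"))
  sm <- result$shell_means
  is_outer <- grepl(">=", as.character(sm$shell))
  sm$limit <- ifelse(is_outer, NA_real_, limit_mm)
  sm$verdict <- ifelse(is_outer, "none",
                       ifelse(is.na(sm$mean_shift), "none",
                              ifelse(sm$mean_shift <= limit_mm, "pass", "fail")))
  sm
}
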