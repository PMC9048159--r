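# Mechanical (laser/couch) accuracy: offsets and rotations of the imaged
# cross-plane phantom relative to the image centre, plus ingestion and
# differencing of ruler-based manual readings.

#' Cross-plane mark set
#'
#' The centre of the cross-planes plus the +-5 cm points on each of the
#' three axes (7 points in all, world mm). Marks may come from manual
#' marking in a planning system or from [auto_locate_cross()].
#'
#' @param centre length-3 numeric, cross centre (mm).
#' @param axis_points 6 x 3 numeric matrix with rows named
#'   `xp, xm, yp, ym, zp, zm` (+/- points on the RL, AP, SI axes).
#' @param source "manual" or "auto".
#' @param max_sagitta_mm collinearity tolerance: the centre must lie within
#'   this distance of the line through each +- pair.
#' @return object of class `cross_mark_set`.
#' @export
cross_mark_set <- function(centre, axis_points, source = c("manual", "auto"),
                           max_sagitta_mm = 5) {
  source <- match.arg(source)
  centre <- as.numeric(centre)
  axis_points <- as.matrix(axis_points)
  if (length(centre) != 3L || !all(is.finite(centre)))
    abort_qa("centre must be 3 finite numbers")
  need <- c("xp", "xm", "yp", "ym", "zp", "zm")
  if (!all(need %in% rownames(axis_points)) || any(!is.finite(axis_points)))
    abort_qa("axis_points must be a finite 6 x 3 matrix with rows xp,xm,yp,ym,zp,zm")
  axis_points <- axis_points[need, ]
  for (ax in c("x", "y", "z")) {
    p <- axis_points[paste0(ax, "p"), ]; m <- axis_points[paste0(ax, "m"), ]
    u <- (p - m); u <- u / sqrt(sum(u^2))
    v <- centre - m
    sag <- sqrt(sum((v - sum(v * u) * u)^2))
    if (sag > max_sagitta_mm)
      abort_qa(sprintf("%s-axis pair not collinear with centre (sagitta %.2f mm)",
                       ax, sag))
  }
  structure(list(centre = centre, axis_points = axis_points, source = source),
            class = "cross_mark_set")
}

secant_angle_deg <- function(delta_out, separation) rad2deg(atan2(delta_out, separation))

#' Translational and rotational offsets of the cross-plane phantom
#'
#' Translations are the RL and AP components of `centre - image_centre`
#' (the SI offset is measured against couch motion by the internal-laser
#' manual test, not from the image). Each rotation is the two-point secant
#' angle of the +-5 cm marks: the mean of the two available pair estimates
#' per axis, mapped to pitch (about RL), roll (about SI) and yaw (about AP)
#' under the package rotation convention.
#'
#' @param marks a [cross_mark_set()].
#' @param image_centre length-3 world point (mm), default the isocentre.
#' @return object of class `mechanical_result`: list with `rl_offset`,
#'   `ap_offset` (mm) and `pitch`, `roll`, `yaw` (degrees).
#' @export
compute_offsets <- function(marks, image_centre = c(0, 0, 0)) {
  stopifnot(inherits(marks, "cross_mark_set"))
  ap <- marks$axis_points
  pair <- function(ax) list(p = ap[paste0(ax, "p"), ], m = ap[paste0(ax, "m"), ])
  sep <- function(pr, axis) (pr$p - pr$m)[axis]
  for (ax in c("x", "y", "z")) {
    pr <- pair(ax)
    if (abs(sep(pr, c(x = 1, y = 2, z = 3)[[ax]])) < 50)
      abort_qa(sprintf("%s-axis pair separation < 50 mm; marks implausible", ax))
  }
  px <- pair("x"); py <- pair("y"); pz <- pair("z")
  sx <- sep(px, 1); sy <- sep(py, 2); sz <- sep(pz, 3)
  # pitch about RL(x): AP pair deviates in SI (+), SI pair deviates in AP (-)
  pitch <- mean(c(secant_angle_deg((py$p - py$m)[3], sy),
                  secant_angle_deg(-(pz$p - pz$m)[2], sz)))
  # roll about SI(z): RL pair deviates in AP (+), AP pair deviates in RL (-)
  roll <- mean(c(secant_angle_deg((px$p - px$m)[2], sx),
                 secant_angle_deg(-(py$p - py$m)[1], sy)))
  # yaw about AP(y): SI pair deviates in RL (+), RL pair deviates in SI (-)
  yaw <- mean(c(secant_angle_deg((pz$p - pz$m)[1], sz),
                secant_angle_deg(-(px$p - px$m)[3], sx)))
  off <- marks$centre - image_centre
  structure(list(rl_offset = off[1], ap_offset = off[2],
                 pitch = pitch, roll = roll, yaw = yaw,
                 source = marks$source),
            class = "mechanical_result")
}

#' @export
print.mechanical_result <- function(x, ...) {
  cat(sprintf(paste0("cross-plane offsets: RL %.3g mm, AP %.3g mm; ",
                     "pitch %.3g, roll %.3g, yaw %.3g deg (%s marks)\n"),
              x$rl_offset, x$ap_offset, x$pitch, x$roll, x$yaw, x$source))
  invisible(x)
}

#' Automatically locate the cross-plane marks in an image
#'
#' The cross centre is the background-subtracted intensity-weighted centroid
#' of all bright cross voxels (the three arms are symmetric about the
#' centre). Each +-5 cm axis point is then the centroid of a short slab of
#' the arm around the nominal position.
#'
#' @param volume an [image_volume()] of the cross-plane phantom.
#' @param arm_length_mm distance of the axis points from the centre, mm.
#' @param threshold_frac detection threshold fraction of (max - background).
#' @return a [cross_mark_set()] with `source = "auto"`.
#' @export
auto_locate_cross <- function(volume, arm_length_mm = 50,
                              threshold_frac = 0.3) {
  arr <- volume$voxels
  bg <- stats::median(arr)
  # reference amplitude from a high quantile of the arm ridge rather than
  # the global max (the triple-overlap centre is ~3x brighter than the arms)
  ref <- stats::quantile(arr, 0.999, names = FALSE)
  thr <- bg + threshold_frac * (ref - bg)
  sel <- which(arr > thr)
  if (length(sel) < 30)
    abort_qa("cross-plane ridges not found; mark the points manually")
  dm <- dim(arr)
  i0 <- sel - 1L
  idx <- cbind(i0 %% dm[1], (i0 %/% dm[1]) %% dm[2], i0 %/% (dm[1] * dm[2]))
  w <- arr[sel] - bg
  pts <- voxel_to_world(volume, idx)
  centre <- colSums(pts * w) / sum(w)

  axis_point <- function(axis, sign) {
    along <- pts[, axis] - centre[axis]
    perp2 <- rowSums(sweep(pts, 2, centre)[, -axis, drop = FALSE]^2)
    # short slab just inside the arm end, so the full tube cross-section
    # contributes to the centroid
    selp <- abs(along - sign * (arm_length_mm - 4)) <= 3 & perp2 <= 8^2
    if (sum(selp) < 3)
      abort_qa("cross-plane arm not found at +-5 cm; mark the points manually")
    colSums(pts[selp, , drop = FALSE] * w[selp]) / sum(w[selp])
  }
  axis_points <- rbind(xp = axis_point(1, 1), xm = axis_point(1, -1),
                       yp = axis_point(2, 1), ym = axis_point(2, -1),
                       zp = axis_point(3, 1), zm = axis_point(3, -1))
  cross_mark_set(centre, axis_points, source = "auto")
}

#' Manual electromechanical test entry
#'
#' One operator-entered ruler/laser reading: the commanded displacement, the
#' measured displacement, and (for movement tests) the reading after the
#' final shift back to zero, used to quantify hysteresis.
#'
#' @param test one of `"lateral_coincidence"`, `"laser_movement"`,
#'   `"el_il_difference"`, `"il_si_offset"`, `"couch_movement"`.
#' @param commanded commanded value, mm.
#' @param measured measured value, mm.
#' @param return_to_zero reading at the return-to-zero position, mm
#'   (movement tests).
#' @return object of class `manual_entry`.
#' @export
manual_entry <- function(test = c("lateral_coincidence", "laser_movement",
                                  "el_il_difference", "il_si_offset",
                                  "couch_movement"),
                         commanded, measured, return_to_zero = NULL) {
  test <- match.arg(test)
  if (!is_num1(commanded) || !is_num1(measured))
    abort_qa("commanded and measured must be finite numbers (mm)")
  structure(list(test = test, commanded = commanded, measured = measured,
                 return_to_zero = return_to_zero),
            class = "manual_entry")
}

#' Evaluate manual electromechanical entries
#'
#' Differences each measured value against its commanded value, extracts
#' hysteresis as the absolute return-to-zero reading of movement tests, and
#' compares differences against the +-2 mm tolerance recommended for
#' radiotherapy laser/couch accuracy. Movement tests without a
#' return-to-zero reading raise a warning.
#'
#' @param entries list of [manual_entry()] objects.
#' @param tolerance_mm tolerance on |measured - commanded|.
#' @return data.frame `test`, `commanded`, `measured`, `difference`,
#'   `hysteresis`, `verdict`.
#' @export
evaluate_manual <- function(entries, tolerance_mm = 2) {
  if (inherits(entries, "manual_entry")) entries <- list(entries)
  stopifnot(all(vapply(entries, inherits, logical(1), "manual_entry")))
  movement <- c("laser_movement", "couch_movement")
  rows <- lapply(entries, function(e) {
    hyst <- NA_real_
    if (e$test %in% movement) {
      if (is.null(e$return_to_zero))
        warning(sprintf("%s: missing return-to-zero reading; hysteresis unknown",
                        e$test), call. = FALSE)
      else hyst <- abs(e$return_to_zero)
    }
    diff <- e$measured - e$commanded
    data.frame(test = e$test, commanded = e$commanded, measured = e$measured,
               difference = diff, hysteresis = hyst,
               verdict = if (abs(diff) <= tolerance_mm) "pass" else "fail")
  })
  do.call(rbind, rows)
}
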