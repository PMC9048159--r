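# PET SUV accuracy: decay-correct the assayed activity to the scan start,
# place a large cylindrical ROI at the phantom centre, and compare the mean
# measured SUV against the uniform-phantom reference of exactly 1.

#' Activity fill record for a uniform PET phantom
#'
#' @param assayed_mbq assayed activity, MBq.
#' @param assay_time assay timestamp (`POSIXct`, or minutes as a number).
#' @param scan_start scan start timestamp (same representation).
#' @param residual_mbq residual syringe activity after filling, MBq.
#' @param residual_time residual assay timestamp; defaults to `assay_time`.
#' @param fill_volume_ml phantom fill volume, ml.
#' @param fill_density_g_ml fill density, g/ml (1.0 for water).
#' @param half_life_min isotope half-life, minutes (109.77 for 18F).
#' @return object of class `activity_record`.
#' @export
activity_record <- function(assayed_mbq, assay_time, scan_start,
                            residual_mbq = 0, residual_time = NULL,
                            fill_volume_ml, fill_density_g_ml = 1.0,
                            half_life_min = 109.77) {
  if (!is_num1(assayed_mbq) || assayed_mbq <= 0)
    abort_qa("assayed activity must be > 0 MBq")
  if (!is_num1(residual_mbq) || residual_mbq < 0)
    abort_qa("residual activity must be >= 0 MBq")
  if (residual_mbq > assayed_mbq)
    abort_qa("residual activity exceeds assayed activity")
  if (!is_num1(fill_volume_ml) || fill_volume_ml <= 0)
    abort_qa("fill volume must be > 0 ml")
  to_min <- function(t) if (inherits(t, "POSIXt")) as.numeric(t) / 60 else
    as.numeric(t)
  at <- to_min(assay_time); st <- to_min(scan_start)
  rt <- if (is.null(residual_time)) at else to_min(residual_time)
  if (at > st) abort_qa("assay must not be after scan start")
  structure(list(assayed_mbq = assayed_mbq, assay_min = at,
                 residual_mbq = residual_mbq, residual_min = rt,
                 scan_min = st, fill_volume_ml = fill_volume_ml,
                 fill_density_g_ml = fill_density_g_ml,
                 half_life_min = half_life_min),
            class = "activity_record")
}

net_activity_bq <- function(rec) {
  stopifnot(inherits(rec, "activity_record"))
  decay <- function(a_mbq, t_min)
    a_mbq * 2^(-(rec$scan_min - t_min) / rec$half_life_min)
  net <- decay(rec$assayed_mbq, rec$assay_min) -
    decay(rec$residual_mbq, rec$residual_min)
  if (net <= 0) abort_qa("non-positive net activity at scan start")
  net * 1e6
}

#' Expected activity concentration at scan start
#'
#' Decays the assayed and residual activities to the scan start time
#' (`A(t) = A0 * 2^(-dt / T_half)`) and divides the net activity by the fill
#' volume.
#'
#' @param rec an [activity_record()].
#' @return expected concentration, Bq/ml.
#' @export
decay_correct <- function(rec) {
  net_activity_bq(rec) / rec$fill_volume_ml
}

#' Place the standard cylindrical SUV ROI at the phantom centre
#'
#' The phantom support is found by thresholding at `support_frac` of the
#' maximum; the ROI is an SI-axis-aligned cylinder (default 18 cm diameter,
#' 18 cm long) centred on the support centroid. The ROI must lie within the
#' phantom (>= `min_inside` of ROI voxels above threshold), otherwise the
#' phantom is too small or mispositioned and an error is raised.
#'
#' @param volume a PET [image_volume()].
#' @param diameter_mm,length_mm ROI dimensions, mm.
#' @param support_frac support threshold as a fraction of the image maximum.
#' @param min_inside minimum fraction of ROI voxels on phantom support.
#' @return logical ROI mask with attribute `centre` (world mm).
#' @export
place_cylinder_roi <- function(volume, diameter_mm = 180, length_mm = 180,
                               support_frac = 0.5, min_inside = 0.99) {
  stopifnot(is_image_volume(volume))
  mx <- max(volume$voxels)
  support <- volume$voxels > support_frac * mx
  if (mx <= 0 || !any(support))
    abort_qa("no phantom support found in the volume")
  dm <- dim(volume$voxels)
  idx <- which(support)
  i0 <- idx - 1L
  ijk <- cbind(i0 %% dm[1], (i0 %/% dm[1]) %% dm[2], i0 %/% (dm[1] * dm[2]))
  centre <- colMeans(voxel_to_world(volume, ijk))

  ax <- axis_coords(volume)
  r2 <- outer((ax$x - centre[1])^2, (ax$y - centre[2])^2, `+`)
  in_xy <- r2 <= (diameter_mm / 2)^2
  in_z <- abs(ax$z - centre[3]) <= length_mm / 2
  roi <- array(FALSE, dm)
  roi[, , in_z] <- in_xy
  frac_inside <- sum(roi & support) / sum(roi)
  if (frac_inside < min_inside)
    abort_qa(sprintf(
      "ROI not contained in phantom support (%.1f%% inside); phantom too small or mispositioned",
      100 * frac_inside))
  attr(roi, "centre") <- centre
  roi
}

#' Mean SUV in the ROI and percent difference to the reference
#'
#' With voxel values in Bq/ml, `SUV = value * fill mass (g) / net activity
#' (Bq)`, so a perfectly calibrated uniform phantom reads SUV = 1
#' everywhere; the reference SUV is therefore exactly 1. Percent difference
#' is `100 * (mean SUV - 1) / 1`.
#'
#' @param volume a PET [image_volume()] in Bq/ml.
#' @param roi ROI mask from [place_cylinder_roi()].
#' @param rec an [activity_record()].
#' @return object of class `suv_result`: list `mean_suv`, `reference_suv`,
#'   `percent_difference`, `roi_voxels`, `expected_concentration` (Bq/ml).
#' @export
suv_difference <- function(volume, roi, rec) {
  stopifnot(is_image_volume(volume))
  if (!identical(volume$units, "Bq/ml"))
    abort_qa("PET volume must be in activity concentration units (Bq/ml)")
  if (!any(roi)) abort_qa("empty ROI")
  net_bq <- net_activity_bq(rec)
  mass_g <- rec$fill_volume_ml * rec$fill_density_g_ml
  suv <- volume$voxels[roi] * mass_g / net_bq
  mean_suv <- mean(suv)
  structure(list(mean_suv = mean_suv, reference_suv = 1,
                 percent_difference = 100 * (mean_suv - 1),
                 roi_voxels = sum(roi),
                 expected_concentration = net_bq / rec$fill_volume_ml),
            class = "suv_result")
}

#' @export
print.suv_result <- function(x, ...) {
  cat(sprintf(
    "mean SUV %.4f (reference 1): %+.2f%% over %d ROI voxels; expected %.0f Bq/ml\n",
    x$mean_suv, x$percent_difference, x$roi_voxels, x$expected_concentration))
  invisible(x)
}
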