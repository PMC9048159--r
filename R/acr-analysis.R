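# ACR-style MR image-quality metrics: slice thickness from the angled-ramp
# profiles, slice position from the crossed-wedge bar lengths, percent
# integral uniformity, ghosting ratio, high-contrast resolution from hole
# arrays, and manual low-contrast scores.

slice_index_at <- function(volume, z) {
  ax <- axis_coords(volume)
  which.min(abs(ax$z - z))
}

region_indices <- function(coords, lim) which(coords >= lim[1] & coords <= lim[2])

# FWHM of a 1-D bar profile with sub-pixel edge interpolation. Half maximum
# is taken relative to the local plateau (profile max) and baseline
# (profile min).
fwhm_length <- function(coords, profile, what = "profile") {
  baseline <- min(profile); plateau <- max(profile)
  half <- baseline + 0.5 * (plateau - baseline)
  if (plateau - baseline <= .Machine$double.eps * 100 ||
      profile[1] >= half || profile[length(profile)] >= half)
    abort_qa(sprintf("%s never crosses half-maximum", what))
  above <- which(profile >= half)
  i1 <- min(above); i2 <- max(above)
  xl <- coords[i1 - 1] + (half - profile[i1 - 1]) /
    (profile[i1] - profile[i1 - 1]) * (coords[i1] - coords[i1 - 1])
  xr <- coords[i2] + (half - profile[i2]) /
    (profile[i2 + 1] - profile[i2]) * (coords[i2 + 1] - coords[i2])
  xr - xl
}

profile_in_box <- function(volume, box, along = c("x", "y")) {
  along <- match.arg(along)
  ax <- axis_coords(volume)
  k <- slice_index_at(volume, box$z)
  ix <- region_indices(ax$x, box$x)
  iy <- region_indices(ax$y, box$y)
  sub <- volume$voxels[ix, iy, k, drop = FALSE]
  if (along == "x")
    list(coords = ax$x[ix], profile = apply(sub, 1, max))
  else
    list(coords = ax$y[iy], profile = apply(sub, 2, max))
}

#' Slice thickness from the angled-ramp profiles
#'
#' Measures the full-width-half-maximum length of the bright bar in each of
#' the two ramp regions and combines them as
#' `thickness = factor * (L_top * L_bottom) / (L_top + L_bottom)`, the
#' harmonic-mean formula that cancels a through-plane position offset for
#' opposed 1:10 ramps (factor 0.2).
#'
#' @param volume an [image_volume()] of the ACR-like phantom.
#' @param cfg an [acr_geometry_config()].
#' @return a [measurement()] in mm.
#' @export
measure_slice_thickness <- function(volume, cfg) {
  stopifnot(inherits(cfg, "acr_geometry_config"))
  lens <- vapply(names(cfg$ramp_regions), function(nm) {
    pr <- profile_in_box(volume, cfg$ramp_regions[[nm]], "x")
    fwhm_length(pr$coords, pr$profile, sprintf("ramp '%s'", nm))
  }, numeric(1))
  thickness <- cfg$ramp_slope_factor * prod(lens) / sum(lens)
  measurement("Slice Thickness", thickness, "mm", test = "acr",
              meta = list(ramp_lengths = lens))
}

#' Slice position offset from the crossed-wedge bar lengths
#'
#' The crossed 45-degree wedges convert a through-plane position offset into
#' an in-plane bar length difference at factor two, so the offset is half
#' the signed difference of the two bar lengths (first minus second).
#'
#' @inheritParams measure_slice_thickness
#' @return a [measurement()] in mm.
#' @export
measure_slice_position <- function(volume, cfg) {
  stopifnot(inherits(cfg, "acr_geometry_config"))
  lens <- vapply(names(cfg$wedge_regions), function(nm) {
    pr <- profile_in_box(volume, cfg$wedge_regions[[nm]], "y")
    fwhm_length(pr$coords, pr$profile, sprintf("wedge bar '%s'", nm))
  }, numeric(1))
  measurement("Slice Position", unname(lens[1] - lens[2]) / 2, "mm",
              test = "acr", meta = list(bar_lengths = lens))
}

#' Percent integral uniformity (PIU)
#'
#' `PIU = 100 * (1 - (high - low) / (high + low))`, where high and low are
#' the means of the brightest and darkest ~1 cm^2 square sub-regions whose
#' window lies entirely inside the uniform-compartment ROI.
#'
#' @inheritParams measure_slice_thickness
#' @return a [measurement()] in %.
#' @export
measure_uniformity <- function(volume, cfg) {
  stopifnot(inherits(cfg, "acr_geometry_config"))
  ur <- cfg$uniform_region
  d_centres <- sqrt(sum((ur$centre - cfg$phantom_centre)^2))
  if (d_centres + ur$radius > cfg$phantom_radius)
    abort_qa("uniformity ROI extends outside the phantom support")
  ax <- axis_coords(volume)
  k <- slice_index_at(volume, ur$z)
  sl <- volume$voxels[, , k]
  w <- max(3L, round(ur$window_mm / volume$spacing[1]))
  # integral image for w x w window means
  nr <- nrow(sl); nc <- ncol(sl)
  s0 <- matrix(0, nr + 1, nc + 1)
  s0[2:(nr + 1), 2:(nc + 1)] <- t(apply(apply(sl, 2, cumsum), 1, cumsum))
  a <- 1:(nr - w + 1); b <- 1:(nc - w + 1)
  sums <- s0[a + w, b + w, drop = FALSE] - s0[a, b + w, drop = FALSE] -
    s0[a + w, b, drop = FALSE] + s0[a, b, drop = FALSE]
  means <- sums / w^2
  # window centre world coordinates
  wc_x <- ax$x[a] + (w - 1) / 2 * volume$spacing[1]
  wc_y <- ax$y[b] + (w - 1) / 2 * volume$spacing[2]
  inside <- outer(wc_x - ur$centre[1], wc_y - ur$centre[2],
                  function(dx, dy) sqrt(dx^2 + dy^2)) <=
    ur$radius - (w / 2) * volume$spacing[1] * sqrt(2)
  if (!any(inside)) abort_qa("uniformity ROI too small for the window size")
  high <- max(means[inside]); low <- min(means[inside])
  piu <- 100 * (1 - (high - low) / (high + low))
  measurement("Image Uniformity", piu, "%", test = "acr",
              meta = list(high = high, low = low))
}

ellipse_mean <- function(sl, ax, e) {
  inside <- outer(((ax$x - e$centre[1]) / e$semi[1])^2,
                  ((ax$y - e$centre[2]) / e$semi[2])^2, `+`) <= 1
  mean(sl[inside])
}

#' Ghosting ratio
#'
#' `100 * |(top + bottom) - (left + right)| / (2 * phantom mean)` over the
#' mean values of four elliptical background ROIs and a large central
#' phantom ROI. Background ROIs must lie wholly outside the phantom.
#'
#' @inheritParams measure_slice_thickness
#' @return a [measurement()] in %.
#' @export
measure_ghosting <- function(volume, cfg) {
  stopifnot(inherits(cfg, "acr_geometry_config"))
  g <- cfg$ghost_rois
  for (nm in c("top", "bottom", "left", "right")) {
    e <- g[[nm]]
    u <- e$centre - cfg$phantom_centre
    d <- sqrt(sum(u^2))
    u <- u / d
    # ellipse support radius toward the phantom centre
    reach <- sqrt((e$semi[1] * u[1])^2 + (e$semi[2] * u[2])^2)
    if (d - reach < cfg$phantom_radius)
      abort_qa(sprintf("background ROI '%s' overlaps the phantom support", nm))
  }
  ax <- axis_coords(volume)
  k <- slice_index_at(volume, g$z)
  sl <- volume$voxels[, , k]
  m <- vapply(c("top", "bottom", "left", "right"),
              function(nm) ellipse_mean(sl, ax, g[[nm]]), numeric(1))
  cen <- g$central
  inside <- outer(ax$x - cen$centre[1], ax$y - cen$centre[2],
                  function(dx, dy) dx^2 + dy^2) <= cen$radius^2
  phantom_mean <- mean(sl[inside])
  ghost <- unname(100 *
    abs((m["top"] + m["bottom"]) - (m["left"] + m["right"])) /
    (2 * phantom_mean))
  measurement("Ghosting", ghost, "%", test = "acr",
              meta = list(roi_means = m, phantom_mean = phantom_mean))
}

resolved_line <- function(coords, profile, n_holes, threshold) {
  n <- length(profile)
  if (n < 3L) return(FALSE)
  loc <- which(profile[2:(n - 1)] >= profile[1:(n - 2)] &
                 profile[2:(n - 1)] >= profile[3:n]) + 1L
  if (length(loc) < n_holes) return(FALSE)
  peaks <- loc[order(profile[loc], decreasing = TRUE)][seq_len(n_holes)]
  peaks <- sort(peaks)
  for (i in seq_len(n_holes - 1L)) {
    seg <- profile[peaks[i]:peaks[i + 1]]
    trough <- min(seg)
    if (!(trough < threshold * min(profile[peaks[i]], profile[peaks[i + 1]])))
      return(FALSE)
  }
  TRUE
}

#' High-contrast spatial resolution from the hole arrays
#'
#' A hole row or column counts as resolved when every inter-hole trough dips
#' below `threshold` (default 0.7) times the smaller adjacent peak; the
#' result is the smallest hole diameter with a resolved horizontal or
#' vertical line. If no array is resolved the largest diameter is returned
#' with a warning and `meta$unresolved = TRUE`.
#'
#' @inheritParams measure_slice_thickness
#' @param threshold trough-to-peak modulation criterion.
#' @return a [measurement()] in mm.
#' @export
assess_resolution <- function(volume, cfg, threshold = 0.7) {
  stopifnot(inherits(cfg, "acr_geometry_config"))
  resolved <- vapply(cfg$hole_arrays, function(ha) {
    pr_row <- profile_in_box(volume, ha$row, "x")
    pr_col <- profile_in_box(volume, ha$col, "y")
    resolved_line(pr_row$coords, pr_row$profile, ha$n_holes, threshold) ||
      resolved_line(pr_col$coords, pr_col$profile, ha$n_holes, threshold)
  }, logical(1))
  diameters <- vapply(cfg$hole_arrays, `[[`, numeric(1), "diameter")
  if (any(resolved)) {
    measurement("Spatial Resolution", min(diameters[resolved]), "mm",
                test = "acr", meta = list(unresolved = FALSE))
  } else {
    warning("no hole array resolved; reporting the largest diameter",
            call. = FALSE)
    measurement("Spatial Resolution", max(diameters), "mm", test = "acr",
                meta = list(unresolved = TRUE))
  }
}

#' Record a manual low-contrast detectability score
#'
#' Low-contrast spoke counting is performed visually by an observer; the
#' score (total visible spokes, 0-40) is stored verbatim with observer
#' metadata and compared against the >= 37 spoke tolerance downstream.
#'
#' @param score integer spoke count in 0..40.
#' @param series `"T1"` or `"T2"`.
#' @param observer observer identifier.
#' @return a [measurement()] in spokes.
#' @export
record_low_contrast <- function(score, series = c("T1", "T2"), observer) {
  series <- match.arg(series)
  if (!is_num1(score) || score != round(score) || score < 0 || score > 40)
    abort_qa("low-contrast score must be an integer in 0..40")
  measurement(sprintf("Low-Contrast Detection (%s)", series), as.numeric(score),
              "spokes", test = "acr",
              meta = list(observer = observer, manual = TRUE))
}
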