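# Synthetic ACR-like image-quality phantom and cross-plane phantom.
#
# The ACR-like generator renders an axial disk phantom with the structures
# the image-quality metrics need, at analytically known locations: two
# angled-ramp bars whose imaged length encodes slice thickness, two wedge
# bars whose length difference encodes slice position, a uniform
# compartment, ghost patches outside the phantom, and hole arrays whose
# peak/trough modulation encodes spatial resolution. Edges are rendered
# with sub-voxel partial-volume coverage so profile interpolation can
# recover lengths below the voxel size.

# Fractional edge profile of the interval [lo, hi] sampled at voxel centres.
# Edges ramp linearly over `edge_mm` (an in-plane PSF stand-in); the
# half-intensity point sits exactly at the interval edge, and with
# edge_mm >= 2 * step the ramp spans at least two samples so linear
# interpolation of the half-maximum crossing is exact.
coverage1d <- function(coords, lo, hi, step, edge_mm = 2 * step) {
  pmax(0, pmin(pmin((hi - coords) / edge_mm + 0.5,
                    (coords - lo) / edge_mm + 0.5), 1))
}

#' ACR geometry configuration
#'
#' World-coordinate geometry of every region the image-quality analyses
#' read. The default matches [gen_acr_like()].
#'
#' @param phantom_centre,phantom_radius phantom disk, mm.
#' @param ramp_slope_factor ramp length-to-thickness factor (0.2 for 1:10
#'   ramps).
#' @param ramp_regions,wedge_regions lists of two boxes
#'   (`list(x = c(lo, hi), y = c(lo, hi), z = z)`).
#' @param uniform_region list `centre` (x, y), `radius`, `z`, `window_mm`.
#' @param ghost_rois list of four ellipses (`centre`, `semi`) on `z`, plus
#'   `central` (`centre`, `radius`).
#' @param hole_arrays list of arrays: `diameter` (mm), `row` and `col`
#'   profile boxes, `n_holes`.
#' @return object of class `acr_geometry_config`.
#' @export
acr_geometry_config <- function(phantom_centre = c(0, 0), phantom_radius = 80,
                                ramp_slope_factor = 0.2,
                                ramp_regions = NULL, wedge_regions = NULL,
                                uniform_region = NULL, ghost_rois = NULL,
                                hole_arrays = NULL) {
  z_struct <- -15; z_res <- 15
  ramp_regions <- ramp_regions %||% list(
    top = list(x = c(-45, 45), y = c(2, 18), z = z_struct),
    bottom = list(x = c(-45, 45), y = c(-18, -2), z = z_struct))
  wedge_regions <- wedge_regions %||% list(
    first = list(x = c(-34, -22), y = c(22, 70), z = z_struct),
    second = list(x = c(22, 34), y = c(22, 70), z = z_struct))
  uniform_region <- uniform_region %||%
    list(centre = c(0, 0), radius = 60, z = 0, window_mm = 9)
  ghost_rois <- ghost_rois %||% list(
    top = list(centre = c(0, 90), semi = c(40, 7)),
    bottom = list(centre = c(0, -90), semi = c(40, 7)),
    left = list(centre = c(-90, 0), semi = c(7, 40)),
    right = list(centre = c(90, 0), semi = c(7, 40)),
    central = list(centre = c(0, 0), radius = 60), z = 0)
  if (is.null(hole_arrays)) {
    hole_arrays <- lapply(seq_along(c(1.1, 1.0, 0.9)), function(a) {
      x0 <- -60 + (a - 1) * 45
      list(diameter = c(1.1, 1.0, 0.9)[a], n_holes = 4L, pitch = 4,
           row = list(x = c(x0 - 2, x0 + 14), y = c(-42, -38), z = z_res),
           col = list(x = c(x0 - 2, x0 + 2), y = c(-60, -44), z = z_res))
    })
  }
  structure(list(phantom_centre = phantom_centre,
                 phantom_radius = phantom_radius,
                 ramp_slope_factor = ramp_slope_factor,
                 ramp_regions = ramp_regions, wedge_regions = wedge_regions,
                 uniform_region = uniform_region, ghost_rois = ghost_rois,
                 hole_arrays = hole_arrays),
            class = "acr_geometry_config")
}

#' Generate synthetic ACR-like T1 and T2 series
#'
#' @param true_thickness true slice thickness, mm.
#' @param position_offset true slice-position offset, mm (half the wedge-bar
#'   length difference).
#' @param uniform_value phantom intensity of the T1 series, a.u. (the T2
#'   series is the same phantom at `t2_scale` times the intensity).
#' @param ghost_fraction injected ghost intensity as a fraction of the
#'   phantom value; the true ghosting ratio is `100 * ghost_fraction` %.
#' @param trough_fractions per-array trough-to-peak fraction of the three
#'   hole arrays (1.1, 1.0, 0.9 mm); arrays with fraction below the analysis
#'   threshold read as resolved.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param t2_scale intensity scale of the T2-like series.
#' @param seed RNG seed.
#' @return list with `t1` and `t2` [image_volume()]s, `config`
#'   (the matching [acr_geometry_config()]) and `truth` (thickness, position
#'   offset, ghosting %, resolvable diameters).
#' @export
gen_acr_like <- function(true_thickness = 5, position_offset = 1.3,
                         uniform_value = 300, ghost_fraction = 0.007,
                         trough_fractions = c(0.3, 0.5, 0.9), noise_sd = 0,
                         t2_scale = 0.8, seed = 1) {
  set.seed(seed)
  cfg <- acr_geometry_config()
  dm <- c(200L, 200L, 7L)
  spacing <- c(1, 1, 5)
  origin <- centred_origin(dm, spacing)
  cx <- origin[1] + (seq_len(dm[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dm[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dm[3]) - 1) * spacing[3]
  insert_bg <- 0.1 * uniform_value

  disk <- outer(cx - cfg$phantom_centre[1], cy - cfg$phantom_centre[2],
                function(a, b) a^2 + b^2) <= cfg$phantom_radius^2
  arr <- array(0, dm)
  for (k in seq_len(dm[3])) arr[, , k] <- disk * uniform_value

  k_struct <- which.min(abs(cz - cfg$ramp_regions$top$z))
  k_res <- which.min(abs(cz - cfg$hole_arrays[[1]]$row$z))
  sl <- arr[, , k_struct]

  put_rect <- function(m, xr, yr, value) {
    covx <- coverage1d(cx, xr[1], xr[2], spacing[1])
    covy <- coverage1d(cy, yr[1], yr[2], spacing[2])
    m + outer(covx, covy) * value
  }
  # ramp insert: dark region with two bright bars whose length encodes
  # thickness = factor * (Lt * Lb) / (Lt + Lb); equal bars of length
  # 2 * thickness / factor give the true value
  rr <- cfg$ramp_regions
  in_insert <- outer(cx >= rr$top$x[1] & cx <= rr$top$x[2],
                     cy >= rr$bottom$y[1] & cy <= rr$top$y[2], `&`)
  sl[in_insert] <- insert_bg
  bar_len <- 2 * true_thickness / cfg$ramp_slope_factor
  sl <- put_rect(sl, c(-bar_len / 2, bar_len / 2), c(4, 16),
                 uniform_value - insert_bg)
  sl <- put_rect(sl, c(-bar_len / 2, bar_len / 2), c(-16, -4),
                 uniform_value - insert_bg)

  # wedge insert: two vertical bars; the first is longer by position_offset,
  # the second shorter, so half the length difference is the true offset
  wr <- cfg$wedge_regions
  in_wedge <- outer(cx >= wr$first$x[1] & cx <= wr$second$x[2],
                    cy >= wr$first$y[1] & cy <= wr$first$y[2], `&`)
  sl[in_wedge] <- insert_bg
  wedge_base <- 40
  y0 <- 25
  sl <- put_rect(sl, c(-32, -24), c(y0, y0 + wedge_base + position_offset),
                 uniform_value - insert_bg)
  sl <- put_rect(sl, c(24, 32), c(y0, y0 + wedge_base - position_offset),
                 uniform_value - insert_bg)
  arr[, , k_struct] <- sl

  # resolution inserts: explicit peak/trough pattern per array
  sl <- arr[, , k_res]
  for (a in seq_along(cfg$hole_arrays)) {
    ha <- cfg$hole_arrays[[a]]
    tf <- trough_fractions[a]
    ix_reg <- which(cx >= ha$row$x[1] - 2 & cx <= ha$col$x[2] + 14)
    iy_reg <- which(cy >= ha$col$y[1] - 2 & cy <= ha$row$y[2] + 2)
    sl[ix_reg, iy_reg] <- insert_bg
    # horizontal row
    jy <- which.min(abs(cy - mean(ha$row$y)))
    x_holes <- min(ha$row$x) + 2 + (seq_len(ha$n_holes) - 1) * ha$pitch
    ix_line <- which(cx >= min(x_holes) & cx <= max(x_holes))
    sl[ix_line, jy] <- tf * uniform_value
    for (xh in x_holes) sl[which.min(abs(cx - xh)), jy] <- uniform_value
    # vertical column
    jx <- which.min(abs(cx - mean(ha$col$x)))
    y_holes <- max(ha$col$y) - 2 - (seq_len(ha$n_holes) - 1) * ha$pitch
    iy_line <- which(cy >= min(y_holes) & cy <= max(y_holes))
    sl[jx, iy_line] <- tf * uniform_value
    for (yh in y_holes) sl[jx, which.min(abs(cy - yh))] <- uniform_value
  }
  arr[, , k_res] <- sl

  # ghost patches on the uniform slice, outside the phantom
  k_unif <- which.min(abs(cz - cfg$ghost_rois$z))
  if (ghost_fraction > 0) {
    sl <- arr[, , k_unif]
    for (nm in c("top", "bottom")) {
      e <- cfg$ghost_rois[[nm]]
      inside <- outer(((cx - e$centre[1]) / e$semi[1])^2,
                      ((cy - e$centre[2]) / e$semi[2])^2, `+`) <= 1
      sl[inside] <- sl[inside] + ghost_fraction * uniform_value
    }
    arr[, , k_unif] <- sl
  }

  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  mk <- function(a, desc) image_volume(a, spacing, origin, modality = "MR",
                                       meta = list(series_description = desc))
  list(t1 = mk(arr, "synthetic ACR T1"),
       t2 = mk(arr * t2_scale, "synthetic ACR T2"),
       config = cfg,
       truth = list(thickness = true_thickness,
                    position_offset = position_offset,
                    ghosting_pct = 100 * ghost_fraction,
                    trough_fractions = trough_fractions))
}

#' Generate a synthetic cross-plane phantom image
#'
#' Three orthogonal 10 cm Gaussian-profile rods crossing at a common centre,
#' rigidly transformed by a known offset/rotation.
#'
#' @param offset a [rigid_transform()] applied to the cross.
#' @param arm_length_mm half-length of each rod, mm.
#' @param tube_sigma_mm Gaussian radius of the rods, mm.
#' @param amplitude rod intensity, a.u.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param voxel_mm isotropic voxel size, mm.
#' @param seed RNG seed.
#' @return list with `volume` and `truth` (the applied transform).
#' @export
gen_cross_phantom <- function(offset = rigid_transform(), arm_length_mm = 50,
                              tube_sigma_mm = 2, amplitude = 100,
                              noise_sd = 0, voxel_mm = 1, seed = 1) {
  set.seed(seed)
  half <- arm_length_mm + 14
  dm <- as.integer(round(2 * half / voxel_mm)) + 1L
  dm <- rep(dm, 3)
  spacing <- rep(voxel_mm, 3)
  origin <- centred_origin(dm, spacing)
  arr <- array(0, dm)
  step <- voxel_mm / 2
  s_vals <- seq(-arm_length_mm, arm_length_mm, by = step)
  for (axis in 1:3) {
    pts <- matrix(0, length(s_vals), 3)
    pts[, axis] <- s_vals
    pts <- apply_rigid(offset, pts)
    # normalise line integral so arms have comparable brightness
    amp <- amplitude * step / (tube_sigma_mm * sqrt(2 * pi))
    for (i in seq_len(nrow(pts))) {
      pt <- gauss_patch(dm, spacing, origin, pts[i, ], amp, tube_sigma_mm)
      if (!is.null(pt))
        arr[pt$xs, pt$ys, pt$zs] <- arr[pt$xs, pt$ys, pt$zs] + pt$patch
    }
  }
  if (noise_sd > 0) arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  vol <- image_volume(arr, spacing, origin, modality = "MR",
                      meta = list(series_description = "synthetic cross-plane"))
  list(volume = vol, truth = offset)
}
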