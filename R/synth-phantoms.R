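# Synthetic phantom image generators with known ground truth.
#
# These stand in for the physical phantoms (large-FOV marker grid, PET-MR
# sphere phantom, alkane diffusion vials, uniform activity cylinder) so
# every analysis can be validated end-to-end against an exact truth. They
# emulate geometry and first-order noise only: no MR relaxation physics, no
# EPI distortion beyond the supplied displacement field, no PET
# reconstruction. Markers and spheres are rendered as isotropic Gaussian
# blobs (sigma = radius/2) so sub-voxel centroid detection is well posed.

# Local Gaussian blob patch; the caller adds it to its array in place (the
# array is never passed through a function, which would force a full copy
# per blob). Returns NULL when the blob lies fully outside the grid.
gauss_patch <- function(dm, spacing, origin, centre, amplitude, sigma) {
  idx <- (centre - origin) / spacing        # 0-based fractional index
  h <- ceiling(3 * sigma / spacing)
  lo <- pmax(floor(idx - h), 0)
  hi <- pmin(ceiling(idx + h), dm - 1)
  if (any(lo > hi)) return(NULL)            # fully outside the grid
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  ex <- exp(-((xs - idx[1]) * spacing[1])^2 / (2 * sigma^2))
  ey <- exp(-((ys - idx[2]) * spacing[2])^2 / (2 * sigma^2))
  ez <- exp(-((zs - idx[3]) * spacing[3])^2 / (2 * sigma^2))
  list(xs = xs + 1, ys = ys + 1, zs = zs + 1,
       patch = amplitude * (ex %o% ey %o% ez))
}

#' Specification of a synthetic distortion-grid phantom
#'
#' Emulates a large field-of-view phantom of ~1,200 spherical markers on a
#' regular grid in a low-signal foam background. The default 11 x 11 x 10
#' extent gives 1,210 markers.
#'
#' @param grid_spacing marker grid pitch, mm.
#' @param extent integer marker counts per axis.
#' @param marker_radius blob radius, mm (rendered as Gaussian, sigma = r/2).
#' @param marker_amplitude peak blob intensity above background, a.u.
#' @param background background intensity, a.u.
#' @param displacement_field `function(p)` mapping an n x 3 matrix of nominal
#'   positions (mm) to an n x 3 matrix of displacements (mm); `NULL` = none.
#' @param jitter_sd per-axis Gaussian jitter SD added to each true marker
#'   centre, mm (models marker seating / detection-scale variation).
#' @param noise_sd Gaussian image noise SD, a.u.
#' @param voxel_mm isotropic voxel size of the generated image, mm.
#' @param padding_mm image margin beyond the outermost nominal marker, mm.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return object of class `grid_phantom_spec`.
#' @export
grid_phantom_spec <- function(grid_spacing = 30, extent = c(11, 11, 10),
                              marker_radius = 6, marker_amplitude = 100,
                              background = 5, displacement_field = NULL,
                              jitter_sd = 0, noise_sd = 1, voxel_mm = 1,
                              padding_mm = 12, seed = 1) {
  extent <- as.integer(extent)
  stopifnot(length(extent) == 3, all(extent >= 2), grid_spacing > 0,
            marker_radius > 0, voxel_mm > 0)
  if (voxel_mm > marker_radius)
    abort_qa("image voxel size must not exceed the marker radius")
  structure(list(grid_spacing = grid_spacing, extent = extent,
                 marker_radius = marker_radius,
                 marker_amplitude = marker_amplitude, background = background,
                 displacement_field = displacement_field,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 voxel_mm = voxel_mm, padding_mm = padding_mm, seed = seed),
            class = "grid_phantom_spec")
}

#' Nominal marker lattice of a grid phantom spec
#' @param spec a [grid_phantom_spec()].
#' @return data.frame `id`, `x`, `y`, `z` (mm), lattice centred on the origin.
#' @export
grid_nominal_positions <- function(spec) {
  g <- expand.grid(i = seq_len(spec$extent[1]) - 1,
                   j = seq_len(spec$extent[2]) - 1,
                   k = seq_len(spec$extent[3]) - 1)
  ctr <- (spec$extent - 1) / 2
  data.frame(id = sprintf("m%04d", seq_len(nrow(g))),
             x = (g$i - ctr[1]) * spec$grid_spacing,
             y = (g$j - ctr[2]) * spec$grid_spacing,
             z = (g$k - ctr[3]) * spec$grid_spacing)
}

#' Generate a synthetic distortion-grid phantom image
#'
#' @param spec a [grid_phantom_spec()].
#' @return list with `volume` (an [image_volume()]) and `truth`: a data.frame
#'   `id`, `x`, `y`, `z` of exact marker centres (nominal + displacement +
#'   jitter) plus `out_of_field` for markers displaced outside the image.
#' @export
gen_grid_phantom <- function(spec) {
  stopifnot(inherits(spec, "grid_phantom_spec"))
  set.seed(spec$seed)
  nom <- grid_nominal_positions(spec)
  pts <- as.matrix(nom[, c("x", "y", "z")])
  if (!is.null(spec$displacement_field)) {
    disp <- spec$displacement_field(pts)
    if (!all(dim(disp) == dim(pts)))
      abort_qa("displacement_field must return an n x 3 matrix")
    pts <- pts + disp
  }
  if (spec$jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$jitter_sd),
                        ncol = 3)

  half <- (spec$extent - 1) / 2 * spec$grid_spacing + spec$padding_mm
  dm <- as.integer(round(2 * half / spec$voxel_mm)) + 1L
  spacing <- rep(spec$voxel_mm, 3)
  origin <- centred_origin(dm, spacing)
  arr <- array(spec$background, dm)
  sigma <- spec$marker_radius / 2
  out_of_field <- logical(nrow(pts))
  lim <- origin + (dm - 1) * spacing
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (any(p < origin + 2) || any(p > lim - 2)) {
      out_of_field[i] <- TRUE
      next
    }
    pt <- gauss_patch(dm, spacing, origin, p, spec$marker_amplitude, sigma)
    if (!is.null(pt))
      arr[pt$xs, pt$ys, pt$zs] <- arr[pt$xs, pt$ys, pt$zs] + pt$patch
  }
  if (spec$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sd)
  vol <- image_volume(arr, spacing, origin, modality = "MR",
                      meta = list(series_description = "synthetic grid phantom"))
  truth <- data.frame(id = nom$id, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      out_of_field = out_of_field)
  list(volume = vol, truth = truth)
}

#' Specification of a synthetic PET-MR alignment sphere phantom
#'
#' Five PET-visible spheres, each flanked by one MR-visible sphere superior
#' and one inferior at `+-mr_offset_si`, so that each MR pair midpoint
#' coincides with its PET sphere by construction. A true rigid misalignment
#' is applied to the PET frame.
#'
#' @param pet_sphere_positions 5 x 3 matrix of nominal sphere centres, mm.
#' @param mr_offset_si SI offset of each flanking MR sphere, mm.
#' @param true_misalignment a [rigid_transform()] applied to the PET frame.
#' @param centroid_noise_sd per-axis SD of random displacement of every
#'   rendered sphere centre, mm.
#' @param sphere_radius rendered blob radius, mm.
#' @param voxel_mm isotropic voxel size, mm.
#' @param seed RNG seed.
#' @return object of class `vqc_phantom_spec`.
#' @export
vqc_phantom_spec <- function(pet_sphere_positions = NULL, mr_offset_si = 18,
                             true_misalignment = rigid_transform(),
                             centroid_noise_sd = 0, sphere_radius = 6,
                             voxel_mm = 1, seed = 1) {
  if (is.null(pet_sphere_positions))
    pet_sphere_positions <- rbind(c(0, 0, 0), c(70, 0, 6), c(-70, 0, -6),
                                  c(0, 70, -6), c(0, -70, 6))
  pet_sphere_positions <- as.matrix(pet_sphere_positions)
  if (!all(dim(pet_sphere_positions) == c(5, 3)))
    abort_qa("exactly 5 PET sphere positions are required")
  structure(list(pet_sphere_positions = pet_sphere_positions,
                 mr_offset_si = mr_offset_si,
                 true_misalignment = true_misalignment,
                 centroid_noise_sd = centroid_noise_sd,
                 sphere_radius = sphere_radius, voxel_mm = voxel_mm,
                 seed = seed),
            class = "vqc_phantom_spec")
}

#' Generate a synthetic PET-MR alignment phantom pair
#'
#' @param spec a [vqc_phantom_spec()].
#' @return list with `mr` and `pet` [image_volume()]s and `truth`, the rigid
#'   transform mapping MR pair midpoints onto PET sphere centroids.
#' @export
gen_vqc_phantom <- function(spec) {
  stopifnot(inherits(spec, "vqc_phantom_spec"))
  set.seed(spec$seed)
  pet_true <- apply_rigid(spec$true_misalignment, spec$pet_sphere_positions)
  mr_true <- rbind(
    sweep(spec$pet_sphere_positions, 2, c(0, 0, spec$mr_offset_si), `+`),
    sweep(spec$pet_sphere_positions, 2, c(0, 0, spec$mr_offset_si), `-`))
  if (spec$centroid_noise_sd > 0) {
    pet_true <- pet_true + matrix(stats::rnorm(15, 0, spec$centroid_noise_sd), 5, 3)
    mr_true <- mr_true + matrix(stats::rnorm(30, 0, spec$centroid_noise_sd), 10, 3)
  }
  all_pts <- rbind(pet_true, mr_true)
  half <- apply(abs(all_pts), 2, max) + spec$sphere_radius * 3 + 6
  dm <- as.integer(round(2 * half / spec$voxel_mm)) + 1L
  spacing <- rep(spec$voxel_mm, 3)
  origin <- centred_origin(dm, spacing)
  sigma <- spec$sphere_radius / 2
  render <- function(pts, amplitude, modality, units = NULL) {
    arr <- array(0, dm)
    for (i in seq_len(nrow(pts))) {
      pt <- gauss_patch(dm, spacing, origin, pts[i, ], amplitude, sigma)
      if (!is.null(pt))
        arr[pt$xs, pt$ys, pt$zs] <- arr[pt$xs, pt$ys, pt$zs] + pt$patch
    }
    image_volume(arr, spacing, origin, modality = modality, units = units)
  }
  list(mr = render(mr_true, 100, "MR"),
       pet = render(pet_true, 10000, "PET", units = "Bq/ml"),
       truth = spec$true_misalignment)
}

#' Specification of a synthetic diffusion-vial phantom
#'
#' Three parallel cylindrical vials with mono-exponential diffusion signal
#' `S(b) = s0 * exp(-b * ADC)` and Rician noise, on an air background. The
#' channel noise SD is the mean in-vial b = `b_values[1]` signal divided by
#' `snr_b50`, and the same SD is applied to every b-value image.
#'
#' @param vial_true_adc per-vial true ADC, mm2/s.
#' @param b_values diffusion weightings, s/mm2, strictly increasing, >= 0.
#' @param s0 unweighted signal, a.u.
#' @param snr_b50 signal-to-noise ratio at the lowest b-value; `Inf` = no noise.
#' @param vial_radius,vial_length vial cylinder dimensions, mm.
#' @param vial_centres_x x positions of the three vial axes, mm.
#' @param voxel_mm isotropic voxel size, mm.
#' @param seed RNG seed.
#' @return object of class `dw_vial_spec`.
#' @export
dw_vial_spec <- function(vial_true_adc = c(0.7e-3, 1.2e-3, 1.7e-3),
                         b_values = c(50, 800), s0 = 1000, snr_b50 = 50,
                         vial_radius = 12, vial_length = 50,
                         vial_centres_x = c(-35, 0, 35), voxel_mm = 1.5,
                         seed = 1) {
  stopifnot(length(vial_true_adc) == 3, all(vial_true_adc > 0),
            all(b_values >= 0), !is.unsorted(b_values, strictly = TRUE),
            s0 > 0, vial_radius > 0)
  if (min(diff(sort(vial_centres_x))) <= 2 * vial_radius)
    abort_qa("vials overlap: increase centre separation or reduce radius")
  structure(list(vial_true_adc = vial_true_adc, b_values = b_values, s0 = s0,
                 snr_b50 = snr_b50, vial_radius = vial_radius,
                 vial_length = vial_length, vial_centres_x = vial_centres_x,
                 voxel_mm = voxel_mm, seed = seed),
            class = "dw_vial_spec")
}

#' Generate synthetic diffusion-weighted vial images
#'
#' @param spec a [dw_vial_spec()].
#' @return list of [image_volume()]s, one per b-value (b-value stored in
#'   `meta$b_value`), plus attribute `truth` with the per-vial ADCs.
#' @export
gen_dw_vials <- function(spec) {
  stopifnot(inherits(spec, "dw_vial_spec"))
  set.seed(spec$seed)
  half <- c(max(abs(spec$vial_centres_x)) + spec$vial_radius + 8,
            spec$vial_radius + 8, spec$vial_length / 2 + 8)
  dm <- as.integer(round(2 * half / spec$voxel_mm)) + 1L
  spacing <- rep(spec$voxel_mm, 3)
  origin <- centred_origin(dm, spacing)
  cx <- origin[1] + (seq_len(dm[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dm[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dm[3]) - 1) * spacing[3]
  in_z <- abs(cz) <= spec$vial_length / 2
  vial_mask <- array(0L, dm)       # 0 = background, 1..3 = vial index
  for (v in 1:3) {
    in_xy <- outer((cx - spec$vial_centres_x[v])^2, cy^2, `+`) <=
      spec$vial_radius^2
    m <- array(FALSE, dm)
    m[, , in_z] <- in_xy
    vial_mask[m] <- v
  }
  sigma_levels <- spec$s0 * exp(-spec$b_values[1] * spec$vial_true_adc)
  sigma <- if (is.finite(spec$snr_b50)) mean(sigma_levels) / spec$snr_b50 else 0
  vols <- lapply(spec$b_values, function(b) {
    arr <- array(0, dm)
    for (v in 1:3)
      arr[vial_mask == v] <- spec$s0 * exp(-b * spec$vial_true_adc[v])
    arr <- add_rician_noise(arr, sigma)
    image_volume(arr, spacing, origin, modality = "MR",
                 meta = list(b_value = b,
                             series_description = "synthetic DW vials"))
  })
  attr(vols, "truth") <- list(adc = spec$vial_true_adc, mask = vial_mask)
  vols
}

#' Specification of a synthetic uniform PET activity phantom
#'
#' @param concentration true activity concentration, Bq/ml.
#' @param cylinder_radius,cylinder_length phantom dimensions, mm.
#' @param noise_model `"gaussian"` (constant SD = `noise_scale`) or
#'   `"scaled-poisson"` (SD = `noise_scale * sqrt(mean)` per voxel,
#'   approximating reconstructed PET noise).
#' @param noise_scale noise amplitude; 0 = noiseless.
#' @param voxel_mm isotropic voxel size, mm.
#' @param seed RNG seed.
#' @return object of class `uniform_pet_spec`.
#' @export
uniform_pet_spec <- function(concentration = 5000, cylinder_radius = 110,
                             cylinder_length = 220,
                             noise_model = c("gaussian", "scaled-poisson"),
                             noise_scale = 0, voxel_mm = 2, seed = 1) {
  noise_model <- match.arg(noise_model)
  stopifnot(concentration > 0, cylinder_radius > 0, cylinder_length > 0)
  structure(list(concentration = concentration,
                 cylinder_radius = cylinder_radius,
                 cylinder_length = cylinder_length, noise_model = noise_model,
                 noise_scale = noise_scale, voxel_mm = voxel_mm, seed = seed),
            class = "uniform_pet_spec")
}

#' Generate a synthetic uniform PET activity volume
#'
#' @param spec a [uniform_pet_spec()].
#' @return an [image_volume()] in Bq/ml.
#' @export
gen_uniform_pet <- function(spec) {
  stopifnot(inherits(spec, "uniform_pet_spec"))
  set.seed(spec$seed)
  half <- c(spec$cylinder_radius + 10, spec$cylinder_radius + 10,
            spec$cylinder_length / 2 + 10)
  dm <- as.integer(round(2 * half / spec$voxel_mm)) + 1L
  spacing <- rep(spec$voxel_mm, 3)
  origin <- centred_origin(dm, spacing)
  cx <- origin[1] + (seq_len(dm[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dm[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dm[3]) - 1) * spacing[3]
  in_xy <- outer(cx^2, cy^2, `+`) <= spec$cylinder_radius^2
  arr <- array(0, dm)
  arr[, , abs(cz) <= spec$cylinder_length / 2] <- in_xy * spec$concentration
  if (spec$noise_scale > 0) {
    sd <- switch(spec$noise_model,
                 gaussian = spec$noise_scale,
                 `scaled-poisson` = spec$noise_scale * sqrt(pmax(arr, 0)))
    arr <- arr + stats::rnorm(length(arr), 0, sd)
  }
  image_volume(arr, spacing, origin, modality = "PET", units = "Bq/ml",
               meta = list(series_description = "synthetic uniform PET"))
}
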