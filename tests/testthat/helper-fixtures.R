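# Shared fixtures, all generated in code at test time.

# smooth radial displacement field: magnitude grows quadratically from 0 at
# the isocentre to max_mm at rmax
radial_field <- function(max_mm = 8, rmax = 260) {
  function(p) {
    r <- sqrt(rowSums(p^2))
    mag <- max_mm * (r / rmax)^2
    (p / pmax(r, 1e-9)) * mag
  }
}

# random rotation matrix with det +1 (QR of a random Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(c(1, 1, det(q)))
}

# random rigid transform with bounded magnitude
random_small_transform <- function(t_max = 5, ang_max = 2) {
  t <- runif(3, -t_max, t_max)
  a <- runif(3, -ang_max, ang_max)
  rigid_transform(t[1], t[2], t[3], pitch = a[1], roll = a[2], yaw = a[3])
}

# small quick grid-phantom spec for detection tests
small_grid_spec <- function(noise_sd = 0, ...) {
  grid_phantom_spec(grid_spacing = 30, extent = c(5, 5, 4), voxel_mm = 1.5,
                    noise_sd = noise_sd, ...)
}

# nominal cross-plane mark layout (centre + +-arm points)
nominal_cross_points <- function(arm = 50) {
  rbind(centre = c(0, 0, 0),
        xp = c(arm, 0, 0), xm = c(-arm, 0, 0),
        yp = c(0, arm, 0), ym = c(0, -arm, 0),
        zp = c(0, 0, arm), zm = c(0, 0, -arm))
}

marks_from_points <- function(pts, source = "manual") {
  cross_mark_set(pts["centre", ], pts[-1, , drop = FALSE], source = source)
}

# uniform axial test volume (identity direction, centred on origin)
flat_volume <- function(dm, spacing, value = 0, modality = "MR", ...) {
  image_volume(array(value, dm), spacing,
               origin = -(dm - 1) / 2 * spacing, modality = modality, ...)
}

# numeric 6-DOF least-squares registration oracle (independent of kabsch_fit)
optim_register <- function(a, b) {
  obj <- function(par) {
    tf <- rigid_transform(par[1], par[2], par[3],
                          pitch = par[4], roll = par[5], yaw = par[6])
    sum((apply_rigid(tf, a) - b)^2)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  fit
}
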