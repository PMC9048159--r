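# helper: paint an axis-aligned bar with linear partial-volume edges into a
# slice of a volume (independent re-implementation for hand oracles)
paint_bar <- function(vol, xr, yr, z, value) {
  ax <- axis_coords(vol)
  k <- which.min(abs(ax$z - z))
  covx <- pmax(0, pmin(pmin((xr[2] - ax$x) / 2 + 0.5,
                            (ax$x - xr[1]) / 2 + 0.5), 1))
  covy <- pmax(0, pmin(pmin((yr[2] - ax$y) / 2 + 0.5,
                            (ax$y - yr[1]) / 2 + 0.5), 1))
  vol$voxels[, , k] <- vol$voxels[, , k] + outer(covx, covy) * value
  vol
}

test_that("slice thickness follows the harmonic-mean ramp formula", {
  g <- gen_acr_like(true_thickness = 5)
  expect_equal(measure_slice_thickness(g$t1, g$config)$value, 5,
               tolerance = 1e-6)
  # unequal ramps: L_top = 60, L_bottom = 42.857 -> 0.2 * prod/sum = 5.0
  vol <- flat_volume(c(200, 200, 7), c(1, 1, 5), value = 0)
  vol <- paint_bar(vol, c(-30, 30), c(4, 16), -15, 300)
  vol <- paint_bar(vol, c(-42.857 / 2, 42.857 / 2), c(-16, -4), -15, 300)
  th <- measure_slice_thickness(vol, acr_geometry_config())
  expect_equal(th$value, 0.2 * (60 * 42.857) / (60 + 42.857),
               tolerance = 1e-4)
  expect_equal(round(th$value, 2), 5.00)
})

test_that("a ramp that never crosses half-maximum raises a named failure", {
  vol <- flat_volume(c(200, 200, 7), c(1, 1, 5), value = 0)
  vol <- paint_bar(vol, c(-30, 30), c(4, 16), -15, 300)  # top ramp only
  expect_error(measure_slice_thickness(vol, acr_geometry_config()),
               "ramp 'bottom'")
})

test_that("slice position is half the wedge-bar length difference", {
  g0 <- gen_acr_like(position_offset = 0)
  expect_equal(measure_slice_position(g0$t1, g0$config)$value, 0,
               tolerance = 1e-9)
  g2 <- gen_acr_like(position_offset = 2)
  expect_equal(measure_slice_position(g2$t1, g2$config)$value, 2,
               tolerance = 0.1)
  g13 <- gen_acr_like(position_offset = 1.3)
  expect_equal(measure_slice_position(g13$t1, g13$config)$value, 1.3,
               tolerance = 0.1)
})

test_that("PIU is 100% on a uniform compartment and matches the hand oracle", {
  g <- gen_acr_like()
  expect_equal(measure_uniformity(g$t1, g$config)$value, 100)
  # inject an 11x11 mm bright and dark patch: high = 100, low = 80
  vol <- flat_volume(c(200, 200, 7), c(1, 1, 5), value = 90)
  ax <- axis_coords(vol)
  hx <- which(abs(ax$x - (-25)) <= 5.5); hy <- which(abs(ax$y) <= 5.5)
  lx <- which(abs(ax$x - 25) <= 5.5)
  vol$voxels[hx, hy, 4] <- 100
  vol$voxels[lx, hy, 4] <- 80
  piu <- measure_uniformity(vol, acr_geometry_config())
  expect_equal(piu$value, 100 * (1 - 20 / 180), tolerance = 1e-6)
  expect_equal(round(piu$value, 1), 88.9)
})

test_that("uniformity ROI outside the phantom support is rejected", {
  g <- gen_acr_like()
  cfg <- g$config
  cfg$uniform_region$centre <- c(50, 0)   # 50 + 60 > 80
  expect_error(measure_uniformity(g$t1, cfg), "outside the phantom")
})

test_that("ghosting matches the four-ROI formula and is zero with no ghost", {
  g0 <- gen_acr_like(ghost_fraction = 0)
  expect_equal(measure_ghosting(g0$t1, g0$config)$value, 0)
  g <- gen_acr_like(ghost_fraction = 0.007)
  expect_equal(measure_ghosting(g$t1, g$config)$value, 0.7, tolerance = 1e-6)
  # hand oracle: top/bottom ellipses 4, left/right 1, phantom mean 300
  cfg <- acr_geometry_config()
  vol <- flat_volume(c(200, 200, 7), c(1, 1, 5), value = 0)
  ax <- axis_coords(vol)
  disk <- outer(ax$x^2, ax$y^2, `+`) <= cfg$phantom_radius^2
  vol$voxels[, , 4][disk] <- 300
  fill_ellipse <- function(vol, e, value) {
    inside <- outer(((ax$x - e$centre[1]) / e$semi[1])^2,
                    ((ax$y - e$centre[2]) / e$semi[2])^2, `+`) <= 1
    vol$voxels[, , 4][inside] <- value
    vol
  }
  vol <- fill_ellipse(vol, cfg$ghost_rois$top, 4)
  vol <- fill_ellipse(vol, cfg$ghost_rois$bottom, 4)
  vol <- fill_ellipse(vol, cfg$ghost_rois$left, 1)
  vol <- fill_ellipse(vol, cfg$ghost_rois$right, 1)
  expect_equal(measure_ghosting(vol, cfg)$value, 100 * abs(8 - 2) / 600,
               tolerance = 1e-9)
})

test_that("background ROIs overlapping the phantom are rejected", {
  g <- gen_acr_like()
  cfg <- g$config
  cfg$ghost_rois$top$centre <- c(0, 70)
  expect_error(measure_ghosting(g$t1, cfg), "overlaps the phantom")
})

test_that("resolution reports the smallest resolved array", {
  g <- gen_acr_like(trough_fractions = c(0.3, 0.5, 0.9))
  expect_equal(assess_resolution(g$t1, g$config)$value, 1.0)
  g_all <- gen_acr_like(trough_fractions = c(0.3, 0.5, 0.6))
  expect_equal(assess_resolution(g_all$t1, g_all$config)$value, 0.9)
  g_none <- gen_acr_like(trough_fractions = c(0.9, 0.95, 0.99))
  expect_warning(res <- assess_resolution(g_none$t1, g_none$config),
                 "no hole array resolved")
  expect_equal(res$value, 1.1)
  expect_true(res$meta$unresolved)
})

test_that("PIU, ghosting and thickness are invariant under global scaling", {
  g <- gen_acr_like()
  scaled <- g$t1; scaled$voxels <- scaled$voxels * 2.7
  expect_equal(measure_uniformity(scaled, g$config)$value,
               measure_uniformity(g$t1, g$config)$value, tolerance = 1e-12)
  expect_equal(measure_ghosting(scaled, g$config)$value,
               measure_ghosting(g$t1, g$config)$value, tolerance = 1e-12)
  expect_equal(measure_slice_thickness(scaled, g$config)$value,
               measure_slice_thickness(g$t1, g$config)$value,
               tolerance = 1e-12)
})

test_that("T2-like series reproduces the same geometry metrics", {
  g <- gen_acr_like()
  expect_equal(measure_slice_thickness(g$t2, g$config)$value, 5,
               tolerance = 1e-6)
  expect_equal(measure_uniformity(g$t2, g$config)$value, 100)
})

test_that("low-contrast scores are stored verbatim and validated", {
  m <- record_low_contrast(35, "T1", observer = "obs1")
  expect_equal(m$value, 35)
  expect_equal(m$meta$observer, "obs1")
  tol <- tolerance_spec(list("Low-Contrast Detection (T1)" = tol_ge(37)))
  expect_equal(apply_tolerance(m, tol)$verdict, "fail")
  expect_equal(apply_tolerance(record_low_contrast(37, "T1", "obs1"),
                               tol)$verdict, "pass")
  expect_error(record_low_contrast(41, "T1", "obs1"), "0..40")
  expect_error(record_low_contrast(3.5, "T1", "obs1"), "integer")
})
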