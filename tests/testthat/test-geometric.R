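test_that("markers are detected at nominal positions on an undistorted grid", {
  spec <- small_grid_spec()
  g <- gen_grid_phantom(spec)
  grid <- reference_grid_from_spec(spec)
  mk <- detect_markers(g$volume, grid)
  expect_equal(nrow(mk), nrow(grid$nominal))
  expect_length(attr(mk, "missing"), 0)
  tr <- g$truth[match(mk$id, g$truth$id), ]
  err <- sqrt((mk$x - tr$x)^2 + (mk$y - tr$y)^2 + (mk$z - tr$z)^2)
  expect_lt(max(err), 0.1)
})

test_that("a deleted marker is reported missing, not detected", {
  spec <- small_grid_spec()
  g <- gen_grid_phantom(spec)
  grid <- reference_grid_from_spec(spec)
  # erase the blob of the first marker from the image
  idx <- round(world_to_voxel(g$volume, unlist(g$truth[1, c("x", "y", "z")])))
  xs <- (idx[1] - 8):(idx[1] + 8) + 1
  g$volume$voxels[xs, (idx[2] - 8):(idx[2] + 8) + 1,
                  (idx[3] - 8):(idx[3] + 8) + 1] <- spec$background
  mk <- detect_markers(g$volume, grid)
  expect_true(g$truth$id[1] %in% attr(mk, "missing"))
  expect_false(g$truth$id[1] %in% mk$id)
})

test_that("two candidates for one ID keep the brighter, report the other spurious", {
  spec <- small_grid_spec()
  g <- gen_grid_phantom(spec)
  grid <- reference_grid_from_spec(spec)
  # add a dimmer decoy blob 13 mm from marker 1
  target <- unlist(g$truth[1, c("x", "y", "z")]) + c(13, 0, 0)
  idx <- round(world_to_voxel(g$volume, target))
  dm <- dim(g$volume$voxels)
  for (dx in -4:4) for (dy in -4:4) for (dz in -4:4) {
    i <- idx + c(dx, dy, dz) + 1
    d <- sqrt(sum((c(dx, dy, dz) * spec$voxel_mm)^2))
    g$volume$voxels[i[1], i[2], i[3]] <-
      g$volume$voxels[i[1], i[2], i[3]] + 40 * exp(-d^2 / (2 * 3^2))
  }
  mk <- detect_markers(g$volume, grid)
  expect_equal(nrow(mk), nrow(grid$nominal))
  m1 <- mk[mk$id == g$truth$id[1], ]
  expect_lt(abs(m1$x - g$truth$x[1]), 1)        # kept the bright true marker
  expect_gte(nrow(attr(mk, "spurious")), 1)
})

test_that("distortion shifts and shells follow the Euclidean definition", {
  spec <- small_grid_spec()
  grid <- reference_grid_from_spec(spec)
  # perfect measurement: shifts all zero
  mk0 <- grid$nominal
  mk0$intensity <- 1
  class(mk0) <- c("marker_set", "data.frame")
  d0 <- compute_distortion(mk0, grid)
  expect_equal(max(d0$per_marker$shift), 0, tolerance = 1e-9)
  expect_true(all(d0$shell_means$mean_shift[!is.na(d0$shell_means$mean_shift)] < 1e-9))
  # a marker displaced by (3,4,0) has shift 5 (setup fit from inner markers
  # is dominated by the unshifted ones)
  mk1 <- mk0
  far <- which.max(mk1$x^2 + mk1$y^2 + mk1$z^2)
  mk1$x[far] <- mk1$x[far] + 3
  mk1$y[far] <- mk1$y[far] + 4
  d1 <- compute_distortion(mk1, grid)
  expect_equal(d1$per_marker$shift[d1$per_marker$id == mk1$id[far]], 5,
               tolerance = 0.03)  # setup fit absorbs ~1/n of the displacement
  # shell partition is exhaustive and disjoint
  expect_equal(sum(table(d1$per_marker$shell)), nrow(mk1))
})

test_that("distortion is invariant under a global rigid motion of the phantom", {
  spec <- small_grid_spec(displacement_field = radial_field(3, 100))
  g <- gen_grid_phantom(spec)
  grid <- reference_grid_from_spec(spec)
  mk <- detect_markers(g$volume, grid)
  # with the setup fit over all markers the least-squares solution composes
  # exactly with the applied motion, so shifts are invariant to precision
  base <- compute_distortion(mk, grid, setup_fit_radius_mm = Inf)
  set.seed(31)
  for (i in 1:5) {
    tf <- random_small_transform(t_max = 5, ang_max = 2)
    moved <- mk
    pts <- apply_rigid(tf, as.matrix(mk[, c("x", "y", "z")]))
    moved$x <- pts[, 1]; moved$y <- pts[, 2]; moved$z <- pts[, 3]
    res <- compute_distortion(moved, grid, setup_fit_radius_mm = Inf)
    expect_lt(max(abs(res$per_marker$shift - base$per_marker$shift)), 1e-6)
    # the default central-marker setup fit stays within marker-subset noise
    res_d <- compute_distortion(moved, grid)
    expect_lt(max(abs(res_d$per_marker$shift - base$per_marker$shift)), 0.2)
  }
})

test_that("per-marker longitudinal statistics match the hand oracle", {
  mk_session <- function(shifts) {
    structure(list(per_marker = data.frame(
      id = sprintf("m%02d", seq_along(shifts)), shift = shifts)),
      class = "distortion_result")
  }
  sessions <- list(mk_session(c(1.0, 2.0)), mk_session(c(1.2, 2.0)),
                   mk_session(c(1.4, 2.0)))
  ls <- longitudinal_stats(sessions)
  expect_equal(ls$per_marker$sd, c(0.2, 0), tolerance = 1e-12)
  expect_equal(ls$mean_sd, 0.1, tolerance = 1e-12)
  expect_equal(ls$mean_range, 0.2, tolerance = 1e-12)
})

test_that("markers absent from any session are excluded and reported", {
  mk_session <- function(ids, shifts) {
    structure(list(per_marker = data.frame(id = ids, shift = shifts)),
              class = "distortion_result")
  }
  sessions <- list(mk_session(c("a", "b", "c"), c(1, 2, 3)),
                   mk_session(c("a", "b"), c(1, 2)),
                   mk_session(c("a", "b", "c"), c(1, 2, 3)))
  ls <- longitudinal_stats(sessions)
  expect_equal(sort(ls$per_marker$id), c("a", "b"))
  expect_equal(ls$excluded$id, "c")
  expect_equal(ls$excluded$n_present, 2L)
  expect_error(longitudinal_stats(sessions[1]), "at least 2")
})

test_that("mean-of-SD statistic equals brute force on random small instances", {
  set.seed(12)
  for (rep in 1:50) {
    n_mark <- sample(2:8, 1)
    n_sess <- sample(2:5, 1)
    shifts <- matrix(abs(rnorm(n_mark * n_sess)), n_mark, n_sess)
    sessions <- lapply(seq_len(n_sess), function(s)
      structure(list(per_marker = data.frame(
        id = sprintf("m%02d", 1:n_mark), shift = shifts[, s])),
        class = "distortion_result"))
    ls <- longitudinal_stats(sessions)
    # brute force: explicit loops
    sds <- numeric(n_mark); rngs <- numeric(n_mark)
    for (m in 1:n_mark) {
      v <- shifts[m, ]
      mu <- sum(v) / n_sess
      sds[m] <- sqrt(sum((v - mu)^2) / (n_sess - 1))
      rngs[m] <- max(v) - min(v)
    }
    expect_equal(ls$mean_sd, mean(sds), tolerance = 1e-12)
    expect_equal(ls$mean_range, mean(rngs), tolerance = 1e-12)
  }
})

test_that("shell tolerance verdicts follow the 2 mm limit with no limit beyond 25 cm", {
  labels <- petmrqa:::shell_labels(c(100, 150, 200, 250))
  res <- structure(list(shell_means = data.frame(
    shell = factor(labels, levels = labels),
    mean_shift = c(0.27, 0.44, 0.82, 2.2, 7.5), n = c(5, 5, 5, 5, 5))),
    class = "distortion_result")
  tol <- check_tolerance(res)
  expect_equal(tol$verdict, c("pass", "pass", "pass", "fail", "none"))
  expect_true(is.na(tol$limit[5]))
  res$shell_means$mean_shift <- rep(0, 5)
  expect_equal(check_tolerance(res)$verdict[1:4], rep("pass", 4))
})
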