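test_that("sphere detection finds the expected counts with sub-voxel accuracy", {
  v <- gen_vqc_phantom(vqc_phantom_spec())
  pet <- detect_spheres(v$pet, 5L)
  mr <- detect_spheres(v$mr, 10L)
  expect_equal(nrow(pet), 5L)
  expect_equal(nrow(mr), 10L)
  truth <- vqc_phantom_spec()$pet_sphere_positions
  d2 <- outer(rowSums(as.matrix(pet[, c("x", "y", "z")])^2),
              rowSums(truth^2), `+`) -
    2 * as.matrix(pet[, c("x", "y", "z")]) %*% t(truth)
  expect_lt(max(apply(sqrt(pmax(d2, 0)), 1, min)), 0.1)
})

test_that("a missing sphere is an error, listing candidates", {
  v <- gen_vqc_phantom(vqc_phantom_spec())
  # erase one PET sphere
  pos <- vqc_phantom_spec()$pet_sphere_positions[2, ]
  idx <- round(world_to_voxel(v$pet, pos))
  v$pet$voxels[(idx[1] - 10):(idx[1] + 10) + 1,
               (idx[2] - 10):(idx[2] + 10) + 1,
               (idx[3] - 10):(idx[3] + 10) + 1] <- 0
  expect_error(detect_spheres(v$pet, 5L), "expected 5 spheres, found 4")
})

test_that("SI pair midpoints are the arithmetic means of the pair centroids", {
  pts <- data.frame(
    x = rep(c(0, 30, -30, 0, 0), 2),
    y = rep(c(0, 0, 0, 30, -30), 2),
    z = c(rep(10, 5), rep(-10, 5)) + c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    intensity = 1, radius_est = 3)
  mids <- mr_pair_midpoints(pts)
  expect_equal(nrow(mids), 5L)
  expect_equal(sort(mids[, 3]), rep(0, 5))
  # explicit example: the pair (0,0,8)/(0,0,12) yields midpoint (0,0,10)
  pts$z[pts$x == 0 & pts$y == 0] <- c(8, 12)
  mids2 <- mr_pair_midpoints(pts)
  hit <- which(abs(mids2[, 1]) < 1e-9 & abs(mids2[, 2]) < 1e-9)
  expect_equal(unname(mids2[hit, 3]), 10, tolerance = 1e-12)
})

test_that("pairing matches an exhaustive minimum-distance matching", {
  set.seed(33)
  layout <- cbind(c(0, 70, -70, 0, 0), c(0, 0, 0, 70, -70),
                  c(0, 6, -6, -6, 6))
  for (rep in 1:20) {
    base <- layout + matrix(runif(15, -5, 5), 5, 3)
    pts <- rbind(base + matrix(c(0, 0, 15), 5, 3, byrow = TRUE),
                 base - matrix(c(0, 0, 15), 5, 3, byrow = TRUE))
    pts <- pts + matrix(rnorm(30, sd = 0.3), 10, 3)
    df <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3])
    mids <- mr_pair_midpoints(df)
    # oracle: each point i in the first half pairs with i + 5
    oracle <- (pts[1:5, ] + pts[6:10, ]) / 2
    worst <- max(vapply(1:5, function(i)
      min(sqrt(colSums((t(mids) - oracle[i, ])^2))), numeric(1)))
    expect_lt(worst, 1e-9)
  }
})

test_that("non-mutual nearest neighbours make pairing fail", {
  # three spheres on one SI line with unequal gaps plus filler pairs
  z <- c(0, 10, 24)
  df <- data.frame(x = c(0, 0, 0, 100, 100, -100, -100, 0, 0, 100),
                   y = c(0, 0, 0, 0, 0, 0, 0, 100, 100, 100),
                   z = c(z, -10, 10, -10, 10, -10, 10, 30))
  expect_error(mr_pair_midpoints(df), "pairing|pair")
})

test_that("registration recovers exact transforms and matches numeric optimisation", {
  set.seed(44)
  for (rep in 1:20) {
    a <- cbind(runif(5, -80, 80), runif(5, -80, 80), runif(5, -30, 30))
    tf <- random_small_transform(t_max = 5, ang_max = 2)
    b <- apply_rigid(tf, a)
    res <- register_alignment(a, b)
    expect_lt(max(abs(res$transform$t - tf$t)), 1e-6)
    expect_lt(max(abs(res$transform$angles - tf$angles)), 1e-6)
    expect_lt(res$residual_rms, 1e-9)
    expect_equal(det(rotation_matrix(res$transform)), 1, tolerance = 1e-9)
  }
  # noisy case: least-squares optimality against a numeric minimiser
  a <- cbind(runif(5, -80, 80), runif(5, -80, 80), runif(5, -30, 30))
  b <- apply_rigid(rigid_transform(1, -2, 0.5, pitch = 0.5), a) +
    matrix(rnorm(15, sd = 0.5), 5, 3)
  res <- register_alignment(a, b)
  opt <- optim_register(a, b)
  expect_lt(5 * res$residual_rms^2, opt$value * (1 + 1e-6))
  expect_equal(res$transform$t, opt$par[1:3], tolerance = 1e-3)
})

test_that("identical point sets register to the identity", {
  a <- cbind(c(0, 50, -50, 0, 0), c(0, 0, 0, 50, -50), c(0, 5, -5, 5, -5))
  res <- register_alignment(a, a)
  expect_equal(res$transform$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(res$transform$angles), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(res$residual_rms, 0, tolerance = 1e-12)
  # pure translation is recovered exactly
  b <- sweep(a, 2, c(1, 2, 3), `+`)
  res_t <- register_alignment(a, b)
  expect_equal(res_t$transform$t, c(1, 2, 3), tolerance = 1e-9)
})

test_that("registration never returns a reflection and is swap-consistent", {
  set.seed(55)
  for (rep in 1:50) {
    a <- matrix(rnorm(15, sd = 50), 5, 3)
    b <- a + matrix(rnorm(15, sd = 2), 5, 3)
    res <- register_alignment(a, b)
    expect_equal(det(rotation_matrix(res$transform)), 1, tolerance = 1e-9)
    swapped <- register_alignment(b, a)
    expect_equal(swapped$residual_rms, res$residual_rms, tolerance = 1e-6)
  }
})

test_that("collinear configurations are rejected", {
  a <- cbind(seq(-40, 40, length.out = 5), 0, 0)
  expect_error(register_alignment(a, a), "collinear|degenerate")
})

test_that("translation noise propagates as sigma over sqrt(k)", {
  set.seed(66)
  s <- 0.5; k <- 5
  base <- cbind(runif(k, -80, 80), runif(k, -80, 80), runif(k, -30, 30))
  base <- sweep(base, 2, colMeans(base))  # the s/sqrt(k) law holds at the
                                          # centroid, where rotation and
                                          # translation errors decouple
  t_rec <- t(vapply(1:1000, function(i) {
    b <- base + matrix(rnorm(3 * k, sd = s), k, 3)
    register_alignment(base, b)$transform$t
  }, numeric(3)))
  emp_sd <- apply(t_rec, 2, sd)
  expect_lt(max(abs(emp_sd - s / sqrt(k)) / (s / sqrt(k))), 0.2)
})

test_that("full alignment pipeline recovers a small misalignment", {
  tt <- rigid_transform(0.5, 0.3, 0.2, pitch = 0.1)
  v <- gen_vqc_phantom(vqc_phantom_spec(true_misalignment = tt, seed = 2))
  al <- analyze_alignment(v$mr, v$pet)
  expect_lt(max(abs(al$transform$t - tt$t)), 0.05)
  expect_lt(max(abs(al$transform$angles - tt$angles)), 0.05)
})
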