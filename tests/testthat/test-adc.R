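make_b_volume <- function(signal, b) {
  image_volume(array(signal, c(4, 4, 4)), c(1, 1, 1), modality = "MR",
               meta = list(b_value = b))
}

test_that("two-point ADC inversion is exact on noiseless mono-exponential data", {
  set.seed(71)
  mask <- list(array(TRUE, c(4, 4, 4)))
  for (i in 1:50) {
    adc_true <- runif(1, 0.5e-3, 2.5e-3)
    b <- sort(runif(2, 0, 1500))
    s0 <- runif(1, 200, 2000)
    lo <- make_b_volume(s0 * exp(-b[1] * adc_true), b[1])
    hi <- make_b_volume(s0 * exp(-b[2] * adc_true), b[2])
    res <- compute_adc(lo, hi, mask)
    expect_equal(res$mean_adc, adc_true, tolerance = 1e-12)
  }
  # S_low = S_high -> ADC exactly 0
  res0 <- compute_adc(make_b_volume(500, 50), make_b_volume(500, 800), mask)
  expect_equal(res0$mean_adc, 0)
})

test_that("b-value metadata and grid compatibility are enforced", {
  mask <- list(array(TRUE, c(4, 4, 4)))
  lo <- make_b_volume(500, 50); hi <- make_b_volume(300, 800)
  no_b <- lo; no_b$meta$b_value <- NULL
  expect_error(compute_adc(no_b, hi, mask), "b-value")
  expect_error(compute_adc(hi, lo, mask), "larger b-value")
  small <- image_volume(array(1, c(3, 3, 3)), c(1, 1, 1), modality = "MR",
                        meta = list(b_value = 50))
  expect_error(compute_adc(small, hi, mask), "grid")
  # all voxels non-positive -> failure
  neg <- make_b_volume(-1, 50)
  expect_error(compute_adc(neg, hi, mask), "excluded")
})

test_that("vial segmentation recovers the rendered vials", {
  dw <- gen_dw_vials(dw_vial_spec(snr_b50 = Inf))
  truth <- attr(dw, "truth")
  masks <- segment_vials(dw[[1]])
  expect_length(masks, 3)
  # masks disjoint
  expect_true(all(masks[[1]] + masks[[2]] + masks[[3]] <= 1))
  # each mask within 5% of the eroded true vial volume
  for (v in 1:3) {
    true_eroded <- sum(erode3d(truth$mask == v))
    expect_lt(abs(sum(masks[[v]]) - true_eroded) / true_eroded, 0.05)
    expect_true(all(truth$mask[masks[[v]]] == v))
  }
})

test_that("a missing vial makes segmentation fail", {
  dw <- gen_dw_vials(dw_vial_spec(snr_b50 = Inf))
  truth <- attr(dw, "truth")
  b50 <- dw[[1]]
  b50$voxels[truth$mask == 2] <- 0
  expect_error(segment_vials(b50), "expected 3 vials")
})

test_that("full ADC pipeline is accurate within 2% at Rician SNR 50", {
  errs <- sapply(1:10, function(seed) {
    spec <- dw_vial_spec(vial_true_adc = c(1.1e-3, 1.1e-3, 1.1e-3),
                         snr_b50 = 50, seed = seed)
    dw <- gen_dw_vials(spec)
    masks <- segment_vials(dw[[1]])
    res <- compute_adc(dw[[1]], dw[[2]], masks)
    max(abs(res$mean_adc - 1.1e-3) / 1.1e-3)
  })
  expect_lt(mean(errs), 0.02)
})

test_that("estimator bias under Rician noise falls monotonically with SNR", {
  set.seed(81)
  adc_true <- 1.1e-3; s0 <- 1000; b <- c(50, 800)
  sig_lo <- s0 * exp(-b[1] * adc_true); sig_hi <- s0 * exp(-b[2] * adc_true)
  # common random numbers across SNR levels so Monte-Carlo error cancels in
  # the bias differences
  n <- 50000
  g1 <- rnorm(n); g2 <- rnorm(n); g3 <- rnorm(n); g4 <- rnorm(n)
  bias_at <- function(snr) {
    sigma <- sig_lo / snr
    s_l <- sqrt((sig_lo + sigma * g1)^2 + (sigma * g2)^2)
    s_h <- sqrt((sig_hi + sigma * g3)^2 + (sigma * g4)^2)
    abs(mean(log(s_l / s_h) / diff(b)) - adc_true)
  }
  biases <- vapply(c(10, 25, 50, 100), bias_at, numeric(1))
  expect_true(all(diff(biases) < 0))
})

test_that("reference ADC interpolation and extrapolation behave as stated", {
  tab <- adc_reference_table(list(
    nonane = data.frame(temperature = c(20, 22), adc = c(2.0e-3, 2.2e-3))))
  expect_equal(reference_adc(tab, "nonane", 20), 2.0e-3)      # node
  expect_equal(reference_adc(tab, "nonane", 21), 2.1e-3)      # midpoint
  expect_error(reference_adc(tab, "nonane", 25), "outside")
  expect_warning(ex <- reference_adc(tab, "nonane", 25, extrapolate = TRUE),
                 "extrapolating")
  expect_equal(ex, 2.5e-3, tolerance = 1e-12)
  expect_error(reference_adc(tab, "decane", 21), "not in reference")
  # invariants of the table itself
  expect_error(adc_reference_table(list(x = data.frame(
    temperature = 20, adc = 1e-3))), ">= 2")
  expect_error(adc_reference_table(list(x = data.frame(
    temperature = c(22, 20), adc = c(1e-3, 1e-3)))), "increasing")
})

test_that("the shipped synthetic reference table loads and interpolates", {
  tab <- read_adc_reference()
  expect_setequal(names(tab$tables), c("nonane", "undecane", "tridecane"))
  for (s in names(tab$tables))
    expect_gt(reference_adc(tab, s, 21.2), 0)
})

test_that("ADC report computes percent differences at the mean temperature", {
  tab <- adc_reference_table(list(
    nonane = data.frame(temperature = c(15, 30), adc = c(1.0e-3, 1.0e-3)),
    undecane = data.frame(temperature = c(15, 30), adc = c(1.0e-3, 1.0e-3)),
    tridecane = data.frame(temperature = c(15, 30), adc = c(1.0e-3, 1.0e-3))))
  adc <- data.frame(vial = 1:3, mean_adc = c(1.0e-3, 1.02e-3, 0.98e-3),
                    n_voxels = 100, n_excluded = 0)
  rep <- adc_report(adc, c("nonane", "undecane", "tridecane"), tab, 21.0, 21.4)
  expect_equal(rep$percent_difference, c(0, 2, -2), tolerance = 1e-9)
  expect_equal(unname(attr(rep, "temperature")["mean"]), 21.2)
  expect_warning(
    adc_report(adc, c("nonane", "undecane", "tridecane"), tab, 20.0, 21.4),
    "not equilibrated")
})

test_that("percent difference antisymmetry identity holds exactly", {
  pd <- function(m, r) 100 * (m - r) / r
  set.seed(91)
  for (i in 1:25) {
    m <- runif(1, 0.5, 2); r <- runif(1, 0.5, 2)
    expect_equal(pd(m, r), -pd(r, m) * (m / r), tolerance = 1e-12)
  }
})

test_that("multi-b log-linear fit matches the two-point estimate on clean data", {
  adc_true <- 1.3e-3; s0 <- 1000
  b <- c(50, 200, 400, 800, 1200)
  vols <- lapply(b, function(bb) make_b_volume(s0 * exp(-bb * adc_true), bb))
  mask <- list(array(TRUE, c(4, 4, 4)))
  res <- compute_adc_multib(vols, mask)
  expect_equal(res$mean_adc, adc_true, tolerance = 1e-12)
})
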