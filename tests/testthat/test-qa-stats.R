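test_that("summary statistics use the sample SD and flag n = 1", {
  s <- summarize_values(c(1.3, 1.3, 1.3))
  expect_equal(s$mean, 1.3); expect_equal(s$sd, 0); expect_equal(s$range, 0)
  s2 <- summarize_values(c(0, 1, 2))
  expect_equal(s2$mean, 1); expect_equal(s2$sd, 1)   # n - 1 denominator
  s1 <- summarize_values(5)
  expect_false(s1$sd_defined); expect_true(is.na(s1$sd))
  expect_error(summarize_values(numeric(0)), "non-empty")
})

test_that("summaries equal a brute-force two-pass oracle", {
  set.seed(9)
  for (i in 1:100) {
    v <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 100))
    s <- summarize_values(v)
    mu <- sum(v) / length(v)
    sd_bf <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    expect_equal(s$mean, mu, tolerance = 1e-12)
    expect_equal(s$sd, sd_bf, tolerance = 1e-12)
    expect_equal(s$range, max(v) - min(v), tolerance = 1e-12)
  }
})

test_that("tolerance verdicts use inclusive bounds", {
  tol <- tolerance_spec(list(
    "Slice Thickness (T1)" = tol_band(5, 0.7),
    "Ghosting (T1)" = tol_le(3),
    "Image Uniformity (T1)" = tol_ge(82),
    "Distortion d>=25cm" = tol_none()))
  expect_equal(apply_tolerance(5.3, tol, "Slice Thickness (T1)")$verdict, "pass")
  expect_equal(apply_tolerance(5.71, tol, "Slice Thickness (T1)")$verdict, "fail")
  expect_equal(apply_tolerance(3.0, tol, "Ghosting (T1)")$verdict, "pass")
  expect_equal(apply_tolerance(82, tol, "Image Uniformity (T1)")$verdict, "pass")
  expect_equal(apply_tolerance(7.5, tol, "Distortion d>=25cm")$verdict, "none")
  expect_error(apply_tolerance(1, tol, "Unknown"), "no tolerance rule")
})

test_that("verdicts are monotone for one-sided rules", {
  tol <- tolerance_spec(list(x = tol_le(2)))
  set.seed(10)
  for (i in 1:50) {
    a <- runif(1, 0, 4)
    if (apply_tolerance(a, tol, "x")$verdict == "pass") {
      b <- runif(1, 0, a)
      expect_equal(apply_tolerance(b, tol, "x")$verdict, "pass")
    }
  }
})

test_that("trend screening flags a real slope and not a constant", {
  flat <- trend_screen(rep(0.5, 12))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_false(flat$flag)
  line <- trend_screen(0.1 * (1:12))
  expect_equal(line$slope, 0.1, tolerance = 1e-9)
  expect_true(line$flag)
  expect_error(trend_screen(1:5), "at least 6")
})

test_that("trend screen false-positive rate is near its nominal level", {
  set.seed(13)
  flags <- vapply(1:1000, function(i) trend_screen(rnorm(30))$flag, logical(1))
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.07)
})

test_that("reports aggregate phases per component with ns noted", {
  sessions <- rbind(
    data.frame(test = "adc", component = "Nonane Difference", units = "%",
               session = sprintf("rep-%d", 1:3), value = c(1, 2, 3),
               phase = "repeatability"),
    data.frame(test = "adc", component = "Nonane Difference", units = "%",
               session = sprintf("m-%02d", 1:11), value = rnorm(11, 3),
               phase = "stability"),
    data.frame(test = "suv", component = "SUV Difference", units = "%",
               session = sprintf("rep-%d", 1:3), value = c(1.3, 1.3, 1.3),
               phase = "repeatability"))
  tol <- tolerance_spec(list("Nonane Difference" = tol_le(5)))
  rep <- render_report(sessions, tol)
  expect_equal(nrow(rep), 2L)
  nr <- rep[rep$component == "Nonane Difference", ]
  expect_equal(nr$repeat_n, 3L)
  expect_equal(nr$stability_n, 11L)       # one missing month noted via n
  expect_equal(nr$repeat_mean, 2)
  expect_equal(nr$repeat_sd, 1)
  expect_equal(nr$verdict, "pass")
  expect_equal(rep[rep$component == "SUV Difference", "verdict"], "none")
})

test_that("mixed units within a component are an error", {
  sessions <- data.frame(test = "acr", component = "Slice Thickness",
                         units = c("mm", "mm", "cm"),
                         session = sprintf("rep-%d", 1:3), value = 1:3,
                         phase = "repeatability")
  expect_error(render_report(sessions), "mixed units")
})

test_that("session JSON round-trips to identical summaries", {
  d <- withr::local_tempdir()
  ms <- list(
    measurement("SUV Difference", 1.3, "%", test = "suv", session = "rep-1"),
    measurement("SUV Difference", 1.8, "%", test = "suv", session = "rep-2"))
  write_session_json(ms, file.path(d, "suv", "rep.json"))
  back <- read_sessions(d)
  expect_equal(nrow(back), 2L)
  orig <- measurements_df(ms)
  expect_equal(summarize_values(back$value)$mean,
               summarize_values(orig$value)$mean, tolerance = 1e-12)
  expect_equal(summarize_values(back$value)$sd,
               summarize_values(orig$value)$sd, tolerance = 1e-12)
  expect_identical(back$value, orig$value)
})
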