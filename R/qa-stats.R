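# Repeatability / stability statistics and tolerance verdicts.
#
# Repeatability is quantified as the sample SD over three same-day
# measurements with independent phantom setups; stability as the SD over
# twelve monthly sessions. Sample SD (n - 1 denominator) is used
# throughout; with n = 3 the denominator choice is material, so it is
# fixed and documented here.

#' A single QA measurement
#'
#' @param component controlled-vocabulary component label (e.g.
#'   `"Slice Thickness (T1)"`).
#' @param value numeric value.
#' @param units unit string, consistent per component.
#' @param test QA test identifier (e.g. `"acr"`, `"distortion"`).
#' @param session session label (e.g. `"2021-03"` or `"repeat-2"`).
#' @param phase `"repeatability"` (same-day repeats) or `"stability"`
#'   (monthly sessions).
#' @param timestamp `POSIXct`.
#' @param meta named list of extra metadata.
#' @return object of class `qa_measurement`.
#' @export
measurement <- function(component, value, units, test = NA_character_,
                        session = NA_character_,
                        phase = c("repeatability", "stability"),
                        timestamp = Sys.time(), meta = list()) {
  phase <- match.arg(phase)
  if (!is_num1(value)) abort_qa("measurement value must be a finite number")
  structure(list(component = component, value = value, units = units,
                 test = test, session = session, phase = phase,
                 timestamp = timestamp, meta = meta),
            class = "qa_measurement")
}

#' @export
print.qa_measurement <- function(x, ...) {
  cat(sprintf("%s: %.4g %s\n", x$component, x$value, x$units))
  invisible(x)
}

#' Convert measurements to a data.frame
#' @param measurements list of [measurement()]s.
#' @return data.frame `test`, `component`, `units`, `session`, `phase`,
#'   `value`.
#' @export
measurements_df <- function(measurements) {
  if (inherits(measurements, "qa_measurement"))
    measurements <- list(measurements)
  do.call(rbind, lapply(measurements, function(m)
    data.frame(test = m$test, component = m$component, units = m$units,
               session = m$session, phase = m$phase, value = m$value)))
}

#' Summary statistics of a measurement series
#'
#' @param values numeric vector (n >= 1).
#' @return object of class `qa_summary`: list `n`, `mean`, `sd` (sample SD,
#'   `NA` with `sd_defined = FALSE` when n = 1), `min`, `max`, `range`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)))
    abort_qa("summarize_values needs a non-empty vector of finite values")
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 sd_defined = length(values) > 1,
                 min = min(values), max = max(values),
                 range = max(values) - min(values)),
            class = "qa_summary")
}

#' Tolerance rules for QA components
#'
#' One rule per component: `le(limit)` (pass when value <= limit),
#' `ge(limit)`, `band(target, half_width)` (inclusive bounds), or `none`.
#'
#' @param rules named list, component -> rule created by [tol_le()],
#'   [tol_ge()], [tol_band()] or [tol_none()].
#' @return object of class `tolerance_spec`.
#' @export
tolerance_spec <- function(rules) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  ok <- vapply(rules, function(r) inherits(r, "qa_tolerance"), logical(1))
  if (!all(ok)) abort_qa("all rules must be tolerance rules")
  structure(list(rules = rules), class = "tolerance_spec")
}

tol_rule <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "qa_tolerance")
}
#' @rdname tolerance_spec
#' @param limit rule limit.
#' @export
tol_le <- function(limit) tol_rule("le", limit = limit)
#' @rdname tolerance_spec
#' @export
tol_ge <- function(limit) tol_rule("ge", limit = limit)
#' @rdname tolerance_spec
#' @param target,half_width band centre and half-width.
#' @export
tol_band <- function(target, half_width) tol_rule("band", target = target,
                                                  half_width = half_width)
#' @rdname tolerance_spec
#' @export
tol_none <- function() tol_rule("none")

#' Apply a tolerance rule to a measurement
#'
#' Bounds are inclusive, matching the use of less/greater-or-equal limits in
#' QA manuals.
#'
#' @param m a [measurement()], `qa_summary` (its mean is tested) or number.
#' @param spec a [tolerance_spec()].
#' @param component component label; taken from `m` when it is a
#'   measurement.
#' @return list `verdict` ("pass"/"fail"/"none"), `rule` (text) and `value`.
#' @export
apply_tolerance <- function(m, spec, component = NULL) {
  stopifnot(inherits(spec, "tolerance_spec"))
  value <- if (inherits(m, "qa_measurement")) m$value
  else if (inherits(m, "qa_summary")) m$mean
  else as.numeric(m)
  component <- component %||%
    (if (inherits(m, "qa_measurement")) m$component else NULL)
  if (is.null(component) || !component %in% names(spec$rules))
    abort_qa(sprintf("no tolerance rule for component '%s'",
                     component %||% "<unknown>"))
  r <- spec$rules[[component]]
  res <- switch(r$type,
    le = list(verdict = if (value <= r$limit) "pass" else "fail",
              rule = sprintf("<= %g", r$limit)),
    ge = list(verdict = if (value >= r$limit) "pass" else "fail",
              rule = sprintf(">= %g", r$limit)),
    band = list(verdict = if (abs(value - r$target) <= r$half_width)
                  "pass" else "fail",
                rule = sprintf("%g +- %g", r$target, r$half_width)),
    none = list(verdict = "none", rule = "none"))
  res$value <- value
  res
}

#' Screen a measurement series for a monotone trend
#'
#' Ordinary least-squares slope of value against session index, flagged when
#' |slope| exceeds twice its standard error. This is a numeric screening
#' aid for longitudinal QA series (which are traditionally judged from
#' plots); it is not a hypothesis test with controlled family-wise error.
#'
#' @param values numeric series in session order (n >= 6).
#' @return list `slope`, `se`, `flag`.
#' @export
trend_screen <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 6L)
    abort_qa("trend screening needs at least 6 sessions")
  idx <- seq_along(values)
  # closed-form OLS (avoids summary.lm warnings on perfectly flat/linear
  # series, which are legitimate QA inputs)
  n <- length(values)
  sxx <- sum((idx - mean(idx))^2)
  slope <- sum((idx - mean(idx)) * (values - mean(values))) / sxx
  resid <- values - mean(values) - slope * (idx - mean(idx))
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(slope = slope, se = se, flag = is.finite(se) && abs(slope) > 2 * se)
}
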