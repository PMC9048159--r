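# Diffusion-weighted MR ADC accuracy: segment the alkane vials on the
# low-b image, estimate the apparent diffusion coefficient from the
# two-point mono-exponential model, and compare against literature
# reference values linearly interpolated at the measured phantom
# temperature.

#' Read a reference ADC table from YAML
#'
#' The table maps each substance to ordered (temperature, ADC) pairs. The
#' file shipped in `inst/extdata/alkane_adc_reference_synthetic.yaml` is a
#' synthetic default of typical published alkane self-diffusion magnitudes
#' and should be replaced by site-validated values for real QA use.
#'
#' @param path YAML file: `substance: {temperature_C: [...], adc_mm2s: [...]}`.
#' @return object of class `reference_adc_table`.
#' @export
read_adc_reference <- function(path = system.file(
  "extdata", "alkane_adc_reference_synthetic.yaml", package = "petmrqa")) {
  raw <- yaml::read_yaml(path)
  tabs <- lapply(raw, function(s)
    data.frame(temperature = as.numeric(s$temperature_C),
               adc = as.numeric(s$adc_mm2s)))
  adc_reference_table(tabs)
}

#' Construct a reference ADC table
#' @param tables named list of data.frames with columns `temperature` (deg C,
#'   strictly increasing, >= 2 rows) and `adc` (mm2/s, > 0).
#' @return object of class `reference_adc_table`.
#' @export
adc_reference_table <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  for (nm in names(tables)) {
    t <- tables[[nm]]
    if (nrow(t) < 2L) abort_qa(sprintf("%s: need >= 2 temperature points", nm))
    if (is.unsorted(t$temperature, strictly = TRUE))
      abort_qa(sprintf("%s: temperatures must be strictly increasing", nm))
    if (any(t$adc <= 0)) abort_qa(sprintf("%s: ADC values must be > 0", nm))
  }
  structure(list(tables = tables), class = "reference_adc_table")
}

#' Reference ADC of a substance at a temperature
#'
#' Piecewise-linear interpolation between the bracketing tabulated
#' temperatures. Queries outside the tabulated range are refused unless
#' `extrapolate = TRUE`, in which case the end segment is extended linearly
#' with a warning.
#'
#' @param table a `reference_adc_table`.
#' @param substance substance name present in the table.
#' @param temperature query temperature, deg C.
#' @param extrapolate allow linear extrapolation outside the table range.
#' @return reference ADC, mm2/s.
#' @export
reference_adc <- function(table, substance, temperature, extrapolate = FALSE) {
  stopifnot(inherits(table, "reference_adc_table"))
  if (!substance %in% names(table$tables))
    abort_qa(sprintf("substance '%s' not in reference table", substance))
  t <- table$tables[[substance]]
  rng <- range(t$temperature)
  if (temperature < rng[1] || temperature > rng[2]) {
    if (!extrapolate)
      abort_qa(sprintf(
        "temperature %.2f C outside reference range [%.2f, %.2f] for %s",
        temperature, rng[1], rng[2], substance))
    warning(sprintf("extrapolating %s reference ADC to %.2f C", substance,
                    temperature), call. = FALSE)
    i <- if (temperature < rng[1]) 1:2 else (nrow(t) - 1):nrow(t)
    slope <- diff(t$adc[i]) / diff(t$temperature[i])
    return(t$adc[i[1]] + slope * (temperature - t$temperature[i[1]]))
  }
  stats::approx(t$temperature, t$adc, xout = temperature)$y
}

#' Segment the diffusion vials on the low-b image
#'
#' Otsu threshold, 3-D connected components, keep the `expected` largest
#' components of plausible size, and erode each by one voxel to avoid edge
#' partial-volume voxels. Masks are returned ordered by the x coordinate of
#' their centroid (matching the left-to-right vial order).
#'
#' @param b50 [image_volume()] of the lowest-b acquisition.
#' @param expected number of vials.
#' @param min_voxels smallest plausible component size before erosion.
#' @return list of `expected` disjoint logical masks.
#' @export
segment_vials <- function(b50, expected = 3L, min_voxels = 30L) {
  stopifnot(is_image_volume(b50))
  thr <- otsu_threshold(b50$voxels)
  lab <- label_components3d(b50$voxels > thr)
  sizes <- attr(lab, "sizes")
  plausible <- which(sizes >= max(min_voxels, 0.1 * max(sizes)))
  if (length(plausible) != expected)
    abort_qa(sprintf("expected %d vials, found %d plausible components (sizes %s)",
                     expected, length(plausible),
                     paste(sizes, collapse = ", ")))
  masks <- lapply(plausible, function(i) erode3d(lab == i))
  if (any(vapply(masks, sum, numeric(1)) == 0))
    abort_qa("vial mask empty after erosion; vials too thin for the voxel size")
  cx <- vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    b50$origin[1] + mean(idx[, 1] - 1) * b50$spacing[1]
  }, numeric(1))
  masks[order(cx)]
}

#' Per-vial mean ADC from two b-values
#'
#' Per-voxel mono-exponential inversion
#' `ADC = ln(S_low / S_high) / (b_high - b_low)` over mask voxels with both
#' signals positive, then the vial value is the mean of the per-voxel ADC
#' map (not the ADC of the mean signals).
#'
#' @param b_low,b_high [image_volume()]s sharing one grid, with `meta$b_value`
#'   set and `b_high` the stronger weighting.
#' @param masks list of vial masks from [segment_vials()].
#' @return data.frame `vial`, `mean_adc` (mm2/s), `n_voxels`, `n_excluded`.
#' @export
compute_adc <- function(b_low, b_high, masks) {
  stopifnot(is_image_volume(b_low), is_image_volume(b_high))
  if (!all(dim(b_low$voxels) == dim(b_high$voxels)))
    abort_qa("b-value volumes must share one voxel grid")
  bl <- b_low$meta$b_value; bh <- b_high$meta$b_value
  if (is.null(bl) || is.null(bh)) abort_qa("b-value metadata missing")
  if (bh <= bl) abort_qa("b_high must carry the larger b-value")
  rows <- lapply(seq_along(masks), function(v) {
    m <- masks[[v]]
    s_l <- b_low$voxels[m]; s_h <- b_high$voxels[m]
    ok <- s_l > 0 & s_h > 0
    if (!any(ok))
      abort_qa(sprintf("vial %d: all voxels excluded (non-positive signal)", v))
    adc <- log(s_l[ok] / s_h[ok]) / (bh - bl)
    data.frame(vial = v, mean_adc = mean(adc), n_voxels = sum(ok),
               n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Multi-b log-linear least-squares ADC fit
#'
#' Validation-mode estimator for acquisitions with more than two b-values:
#' per-voxel slope of `-ln S` against b by ordinary least squares, averaged
#' over each vial mask.
#'
#' @param volumes list of [image_volume()]s with `meta$b_value` set.
#' @param masks list of vial masks.
#' @return data.frame `vial`, `mean_adc`, `n_voxels`.
#' @export
compute_adc_multib <- function(volumes, masks) {
  b <- vapply(volumes, function(v) v$meta$b_value %||% NA_real_, numeric(1))
  if (anyNA(b) || length(b) < 3L)
    abort_qa("need >= 3 volumes with b-value metadata")
  bc <- b - mean(b)
  rows <- lapply(seq_along(masks), function(v) {
    m <- masks[[v]]
    s <- vapply(volumes, function(vol) vol$voxels[m], numeric(sum(m)))
    s <- matrix(s, ncol = length(b))
    ok <- rowSums(s <= 0) == 0
    if (!any(ok)) abort_qa(sprintf("vial %d: all voxels excluded", v))
    ls <- log(s[ok, , drop = FALSE])
    slope <- (ls %*% bc) / sum(bc^2)        # per-voxel OLS slope of ln S vs b
    data.frame(vial = v, mean_adc = mean(-slope), n_voxels = sum(ok))
  })
  do.call(rbind, rows)
}

#' ADC accuracy report against temperature-interpolated references
#'
#' The reference is evaluated at the mean of the pre- and post-acquisition
#' phantom temperatures; a difference above 1 deg C between the readings
#' raises a non-equilibrated-phantom warning. Percent difference is
#' `100 * (measured - reference) / reference`.
#'
#' @param adc data.frame from [compute_adc()].
#' @param substances character vector naming the substance of each vial, in
#'   vial order.
#' @param table a `reference_adc_table`.
#' @param temp_pre,temp_post phantom temperature before/after acquisition,
#'   deg C.
#' @param extrapolate passed to [reference_adc()].
#' @return object of class `adc_result`: data.frame `vial`, `substance`,
#'   `mean_adc`, `reference_adc`, `percent_difference`, `n_voxels`, with the
#'   temperatures as attributes.
#' @export
adc_report <- function(adc, substances, table, temp_pre, temp_post,
                       extrapolate = FALSE) {
  if (length(substances) != nrow(adc))
    abort_qa("one substance per vial is required")
  if (abs(temp_pre - temp_post) > 1)
    warning(sprintf(
      "phantom temperature drifted %.2f C during acquisition; not equilibrated",
      abs(temp_pre - temp_post)), call. = FALSE)
  temp <- mean(c(temp_pre, temp_post))
  ref <- vapply(substances, function(s)
    reference_adc(table, s, temp, extrapolate), numeric(1))
  out <- data.frame(vial = adc$vial, substance = substances,
                    mean_adc = adc$mean_adc, reference_adc = ref,
                    percent_difference = 100 * (adc$mean_adc - ref) / ref,
                    n_voxels = adc$n_voxels)
  attr(out, "temperature") <- c(pre = temp_pre, post = temp_post, mean = temp)
  class(out) <- c("adc_result", "data.frame")
  out
}
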