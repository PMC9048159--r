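# Minimal DICOM I/O (Explicit VR Little Endian only).
#
# The QA analyses only need uncompressed single-frame grayscale series with
# standard geometry tags, so the package carries a small reader/writer pair
# rather than a full DICOM stack. The writer doubles as the fixture writer
# for the synthetic phantom generators, so analyses exercise the same
# ingestion path as scanner data.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.9.7433"

SOP_CLASS <- c(MR = "1.2.840.10008.5.1.4.1.1.4",
               PET = "1.2.840.10008.5.1.4.1.1.128")

uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

#' Generate a DICOM UID under the package root
#' @return a UID string.
#' @export
dicom_uid <- function() {
  sprintf("%s.%d.%d.%d", UID_ROOT,
          as.integer(Sys.time()) %% 100000000L,
          Sys.getpid() %% 100000L, uid_counter())
}

# ---- encoding helpers -------------------------------------------------------

raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
KNOWN_VRS <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
               "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL",
               "US", LONG_VRS)

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  hdr <- c(raw_uint16(group), raw_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), raw_uint32(length(value_raw)), value_raw)
  } else {
    if (length(value_raw) > 65534) abort_qa("DICOM element too long for short VR")
    c(hdr, raw_uint16(length(value_raw)), value_raw)
  }
}

el_str <- function(group, element, vr, x)
  dcm_element(group, element, vr, charToRaw(paste(x, collapse = "\\")))
el_ds <- function(group, element, x)
  el_str(group, element, "DS", sprintf("%.8g", x))
el_us <- function(group, element, x)
  dcm_element(group, element, "US",
              writeBin(as.integer(x), raw(), size = 2, endian = "little"))
el_fd <- function(group, element, x)
  dcm_element(group, element, "FD",
              writeBin(as.numeric(x), raw(), size = 8, endian = "little"))

# ---- writer -----------------------------------------------------------------

#' Write an image volume as a DICOM series
#'
#' One file per slice, Explicit VR Little Endian, 16-bit unsigned pixels with
#' rescale slope/intercept. Integer-valued volumes within the 16-bit range are
#' stored losslessly (slope 1, intercept 0); other volumes are linearly
#' mapped onto the stored range.
#'
#' @param volume an [image_volume()].
#' @param directory output directory (created if needed).
#' @param series_uid series instance UID; default freshly generated. Supplying
#'   different UIDs for files in one directory lets tests exercise the
#'   mixed-series rejection in [load_series()].
#' @param series_description series description string.
#' @param rescale optional `c(intercept, slope)` override.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(volume, directory, series_uid = dicom_uid(),
                               series_description = "petmrqa synthetic",
                               rescale = NULL) {
  stopifnot(is_image_volume(volume))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  vox <- volume$voxels
  dm <- dim(vox)
  if (is.null(rescale)) {
    vmin <- min(vox); vmax <- max(vox)
    if (all(vox == round(vox)) && vmin >= 0 && vmax <= 65535) {
      rescale <- c(0, 1)
    } else {
      slope <- if (vmax > vmin) (vmax - vmin) / 65000 else 1
      rescale <- c(vmin, slope)
    }
  }
  stored <- round((vox - rescale[1]) / rescale[2])
  if (min(stored) < 0 || max(stored) > 65535)
    abort_qa("stored pixel values out of 16-bit range; adjust rescale")
  study_uid <- dicom_uid()
  sop_class <- SOP_CLASS[[volume$modality]]
  acq <- volume$acquisition_time
  acq_date <- if (!is.null(acq)) format(acq, "%Y%m%d") else "20260101"
  acq_time <- if (!is.null(acq)) format(acq, "%H%M%OS6") else "120000.000000"
  d <- volume$direction
  for (k in seq_len(dm[3])) {
    sop_uid <- dicom_uid()
    ipp <- volume$origin + d[, 3] * volume$spacing[3] * (k - 1)
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      el_str(0x0002, 0x0002, "UI", sop_class),
      el_str(0x0002, 0x0003, "UI", sop_uid),
      el_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
      el_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
    meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_uint32(length(meta))), meta)
    body <- c(
      el_str(0x0008, 0x0016, "UI", sop_class),
      el_str(0x0008, 0x0018, "UI", sop_uid),
      el_str(0x0008, 0x0022, "DA", acq_date),
      el_str(0x0008, 0x0032, "TM", acq_time),
      el_str(0x0008, 0x0060, "CS", if (volume$modality == "PET") "PT" else "MR"),
      el_str(0x0008, 0x103E, "LO", series_description),
      el_ds(0x0018, 0x0050, volume$spacing[3]),
      el_ds(0x0018, 0x0088, volume$spacing[3]),
      if (!is.null(volume$meta$b_value))
        el_fd(0x0018, 0x9087, volume$meta$b_value) else raw(0),
      el_str(0x0020, 0x000D, "UI", study_uid),
      el_str(0x0020, 0x000E, "UI", series_uid),
      el_str(0x0020, 0x0013, "IS", as.character(k)),
      el_ds(0x0020, 0x0032, ipp),
      el_ds(0x0020, 0x0037, c(d[, 1], d[, 2])),
      el_us(0x0028, 0x0002, 1L),
      el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      el_us(0x0028, 0x0010, dm[2]),  # Rows (y)
      el_us(0x0028, 0x0011, dm[1]),  # Columns (x)
      el_ds(0x0028, 0x0030, c(volume$spacing[2], volume$spacing[1])),
      el_us(0x0028, 0x0100, 16L),
      el_us(0x0028, 0x0101, 16L),
      el_us(0x0028, 0x0102, 15L),
      el_us(0x0028, 0x0103, 0L),
      el_ds(0x0028, 0x1052, rescale[1]),
      el_ds(0x0028, 0x1053, rescale[2]),
      if (volume$modality == "PET")
        el_str(0x0054, 0x1001, "CS", "BQML") else raw(0),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(stored[, , k]), raw(), size = 2,
                           endian = "little")))
    path <- file.path(directory, sprintf("IM%04d.dcm", k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(directory)
}

# ---- reader -----------------------------------------------------------------

read_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    abort_qa(sprintf("%s: not a DICOM file (missing DICM magic)", path))
  o <- 132L
  n <- length(bytes)
  tags <- new.env(parent = emptyenv())
  u16 <- function(i) readBin(bytes[(i + 1):(i + 2)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(bytes[(i + 1):(i + 4)], "integer", size = 4,
                             endian = "little")
  while (o + 8 <= n) {
    group <- u16(o); element <- u16(o + 2L)
    vr <- rawToChar(bytes[(o + 5):(o + 6)])
    if (!(vr %in% KNOWN_VRS))
      abort_qa(sprintf(
        "%s: unsupported encoding at tag (%04X,%04X); only Explicit VR Little Endian is supported",
        path, group, element))
    if (vr %in% LONG_VRS) {
      len <- u32(o + 8L); data_off <- o + 12L
    } else {
      len <- u16(o + 6L); data_off <- o + 8L
    }
    if (data_off + len > n)
      abort_qa(sprintf("%s: truncated element (%04X,%04X)", path, group, element))
    key <- sprintf("%04X%04X", group, element)
    assign(key, list(vr = vr,
                     raw = if (len > 0) bytes[(data_off + 1):(data_off + len)]
                           else raw(0)),
           envir = tags)
    if (key == "00020010") {
      ts <- dcm_get_str(tags, "00020010")
      if (!identical(ts, TS_EXPLICIT_LE))
        abort_qa(sprintf("%s: unsupported transfer syntax %s", path, ts))
    }
    o <- data_off + len
  }
  tags
}

dcm_get <- function(tags, key) {
  if (!exists(key, envir = tags, inherits = FALSE)) NULL
  else get(key, envir = tags, inherits = FALSE)
}
dcm_get_str <- function(tags, key) {
  e <- dcm_get(tags, key)
  if (is.null(e)) return(NULL)
  r <- e$raw
  while (length(r) && r[length(r)] %in% as.raw(c(0L, 32L))) r <- r[-length(r)]
  trimws(rawToChar(r))
}
dcm_get_nums <- function(tags, key) {
  s <- dcm_get_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_get_us <- function(tags, key) {
  e <- dcm_get(tags, key)
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2, signed = FALSE,
          endian = "little")
}
dcm_get_fd <- function(tags, key) {
  e <- dcm_get(tags, key)
  if (is.null(e)) return(NULL)
  readBin(e$raw, "double", n = length(e$raw) / 8, size = 8, endian = "little")
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Load a DICOM series from a directory
#'
#' Reads every `.dcm` file in `directory`, checks they form one spatially
#' consistent series, sorts slices by position along the slice normal,
#' applies the rescale slope/intercept and assembles an [image_volume()].
#'
#' @param directory path containing exactly one DICOM series.
#' @return an [image_volume()] with geometry from the per-slice metadata;
#'   diffusion b-value (s/mm2) in `meta$b_value` when present.
#' @export
load_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) abort_qa(sprintf("no .dcm files in %s", directory))
  slices <- lapply(files, read_dicom_file)

  uids <- vapply(slices, function(t) dcm_get_str(t, "0020000E") %||% "<missing>",
                 character(1))
  if (length(unique(uids)) > 1L)
    abort_qa(sprintf("mixed series in %s: series UIDs %s", directory,
                     paste(unique(uids), collapse = ", ")))

  need <- c(IPP = "00200032", IOP = "00200037", PixelSpacing = "00280030",
            Rows = "00280010", Columns = "00280011")
  for (i in seq_along(slices)) {
    missing_tags <- names(need)[vapply(need, function(k)
      is.null(dcm_get(slices[[i]], k)), logical(1))]
    if (length(missing_tags))
      abort_qa(sprintf("%s: missing geometry tags: %s", files[i],
                       paste(missing_tags, collapse = ", ")))
  }

  iop <- dcm_get_nums(slices[[1]], "00200037")
  row_dir <- iop[1:3]; col_dir <- iop[4:6]
  normal <- cross3(row_dir, col_dir)
  pos <- t(vapply(slices, function(t) dcm_get_nums(t, "00200032"), numeric(3)))
  proj <- drop(pos %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; pos <- pos[ord, , drop = FALSE]; proj <- proj[ord]

  nx <- dcm_get_us(slices[[1]], "00280011")
  ny <- dcm_get_us(slices[[1]], "00280010")
  ps <- dcm_get_nums(slices[[1]], "00280030")  # (row spacing = y, col = x)
  nz <- length(slices)
  if (nz > 1L) {
    dz_all <- diff(proj)
    dz <- stats::median(dz_all)
    if (dz <= 0 || any(abs(dz_all - dz) > 0.01 * dz))
      abort_qa(sprintf("inconsistent slice spacing in %s (range %.4g..%.4g mm)",
                       directory, min(dz_all), max(dz_all)))
  } else {
    dz <- dcm_get_nums(slices[[1]], "00180088") %||%
      dcm_get_nums(slices[[1]], "00180050") %||% 1
  }

  vox <- array(0, c(nx, ny, nz))
  b_values <- numeric(0)
  for (k in seq_len(nz)) {
    t <- slices[[k]]
    pd <- dcm_get(t, "7FE00010")
    if (is.null(pd)) abort_qa(sprintf("slice %d: missing pixel data", k))
    stored <- readBin(pd$raw, "integer", n = nx * ny, size = 2, signed = FALSE,
                      endian = "little")
    slope <- (dcm_get_nums(t, "00281053") %||% 1)[1]
    inter <- (dcm_get_nums(t, "00281052") %||% 0)[1]
    vox[, , k] <- stored * slope + inter
    bv <- dcm_get_fd(t, "00189087")
    if (!is.null(bv)) b_values <- c(b_values, bv[1])
  }

  modality <- dcm_get_str(slices[[1]], "00080060") %||% "MR"
  if (!modality %in% c("MR", "PET", "PT")) modality <- "MR"
  if (modality == "PT") modality <- "PET"
  units_tag <- dcm_get_str(slices[[1]], "00541001")
  units <- if (identical(units_tag, "BQML")) "Bq/ml" else units_tag
  acq_date <- dcm_get_str(slices[[1]], "00080022")
  acq_time <- dcm_get_str(slices[[1]], "00080032")
  acq <- if (!is.null(acq_date) && !is.null(acq_time))
    as.POSIXct(paste(acq_date, acq_time), format = "%Y%m%d %H%M%OS", tz = "UTC")
  else NULL

  meta <- list(series_description = dcm_get_str(slices[[1]], "0008103E"))
  if (length(b_values)) {
    if (length(unique(b_values)) > 1L)
      abort_qa("slices carry differing diffusion b-values")
    meta$b_value <- b_values[1]
  }
  direction <- cbind(row_dir, col_dir, normal)
  dimnames(direction) <- NULL
  image_volume(vox, spacing = c(ps[2], ps[1], dz), origin = pos[1, ],
               direction = direction, modality = modality,
               units = units %||% "a.u.", acquisition_time = acq, meta = meta)
}
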