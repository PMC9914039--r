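#' Write an image stack to disk
#'
#' Two on-disk dialects are supported.
#'
#' `raw_stack`: one little-endian 32-bit-float voxel file (`<path>.raw`) plus a
#' plain-text sidecar header (`<path>.hdr`) recording dimensions, spacing,
#' dtype and byte order. Voxels are written slice-major, row-major within each
#' slice. The dialect is fixed bit-exactly so fixtures are portable.
#'
#' `dicom_series`: `path` is a directory receiving one uncompressed
#' explicit-VR little-endian CT file per slice with Rows/Columns, PixelSpacing,
#' SliceThickness, ImagePositionPatient and RescaleSlope/Intercept set. HU are
#' stored as signed 16-bit integers with slope 1 / intercept -1024, so HU
#' round-trip to within the integer quantisation.
#'
#' @param stack an [image_stack].
#' @param path base path (`raw_stack`, extensions are appended) or directory
#'   (`dicom_series`).
#' @param format `"raw_stack"` or `"dicom_series"`.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, format = c("raw_stack", "dicom_series")) {
  format <- match.arg(format)
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  if (!all(is.finite(stack$voxels))) {
    stopf("refusing to write stack containing non-finite voxel values")
  }
  switch(format,
         raw_stack = write_raw_stack(stack, path),
         dicom_series = write_dicom_series(stack, path))
  invisible(path)
}

#' Read an image stack from disk
#'
#' Inverse of [write_stack()]. For DICOM series all slices must share pixel
#' spacing, orientation and matrix size; stored values are converted to HU via
#' the per-file RescaleSlope/RescaleIntercept and slices are ordered by their
#' position along the slice axis.
#'
#' @param path base path (`raw_stack`) or directory of `.dcm` files
#'   (`dicom_series`).
#' @param format `"raw_stack"` or `"dicom_series"`.
#' @return An [image_stack].
#' @export
read_stack <- function(path, format = c("raw_stack", "dicom_series")) {
  format <- match.arg(format)
  switch(format,
         raw_stack = read_raw_stack(path),
         dicom_series = read_dicom_series(path))
}

## ---- raw_stack dialect ----------------------------------------------------

write_raw_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  raw_file <- paste0(path, ".raw")
  hdr_file <- paste0(path, ".hdr")
  con <- file(raw_file, open = "wb")
  on.exit(close(con), add = TRUE)
  for (s in seq_len(d[1])) {
    # t() turns R's column-major slice into a row-major vector
    writeBin(as.numeric(t(stack$voxels[s, , ])), con, size = 4L,
             endian = "little")
  }
  hdr <- c(
    "format: raw_stack v1",
    sprintf("n_slices: %d", d[1]),
    sprintf("n_rows: %d", d[2]),
    sprintf("n_cols: %d", d[3]),
    sprintf("pixel_spacing_row_mm: %.10g", stack$pixel_spacing_mm[1]),
    sprintf("pixel_spacing_col_mm: %.10g", stack$pixel_spacing_mm[2]),
    sprintf("slice_thickness_mm: %.10g", stack$slice_thickness_mm),
    "dtype: float32",
    "byte_order: little",
    "voxel_order: slice-major, row-major within slice"
  )
  writeLines(hdr, hdr_file)
  invisible(path)
}

read_raw_stack <- function(path) {
  raw_file <- paste0(path, ".raw")
  hdr_file <- paste0(path, ".hdr")
  if (!file.exists(hdr_file)) stopf("raw_stack header not found: %s", hdr_file)
  if (!file.exists(raw_file)) stopf("raw_stack voxel file not found: %s", raw_file)
  lines <- readLines(hdr_file)
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  getv <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stopf("raw_stack header missing key '%s'", k)
    vals[i]
  }
  ns <- as.integer(getv("n_slices"))
  nr <- as.integer(getv("n_rows"))
  nc <- as.integer(getv("n_cols"))
  con <- file(raw_file, open = "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, numeric(), n = ns * nr * nc, size = 4L, endian = "little")
  if (length(v) != ns * nr * nc) {
    stopf("raw_stack voxel file is truncated: expected %d values, got %d",
          ns * nr * nc, length(v))
  }
  vox <- array(NA_real_, c(ns, nr, nc))
  per <- nr * nc
  for (s in seq_len(ns)) {
    # stored row-major: fill a col x row matrix then transpose
    vox[s, , ] <- t(matrix(v[((s - 1) * per + 1):(s * per)], nrow = nc))
  }
  image_stack(vox,
              pixel_spacing_mm = c(as.numeric(getv("pixel_spacing_row_mm")),
                                   as.numeric(getv("pixel_spacing_col_mm"))),
              slice_thickness_mm = as.numeric(getv("slice_thickness_mm")))
}

## ---- minimal DICOM (explicit VR little endian, uncompressed) --------------
## Only the tag subset needed for calibrated CT slices is handled. No R DICOM
## reader is available to this package, so the subset is implemented here.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.8.498"

uint16_le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 0xFFL), bitwAnd(bitwShiftR(x, 8L), 0xFFL)))
}

uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# Encode one explicit-VR data element.
dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    bytes <- charToRaw(value)
    if (length(bytes) %% 2L == 1L) bytes <- c(bytes, pad)
  } else if (vr == "US") {
    bytes <- uint16_le(value)
  } else {
    bytes <- value  # already raw
  }
  head <- c(uint16_le(group), uint16_le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), uint32_le(length(bytes)), bytes)
  } else {
    c(head, uint16_le(length(bytes)), bytes)
  }
}

dcm_ds <- function(x) {
  paste(vapply(x, function(v) formatC(v, format = "g", digits = 10), ""),
        collapse = "\\")
}

write_dicom_series <- function(stack, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(stack$voxels)
  if (d[2] > 65535 || d[3] > 65535) stopf("matrix too large for DICOM tags")
  intercept <- -1024
  slope <- 1
  # series identity only; avoid touching the user's RNG stream
  series_uid <- paste0(UID_ROOT, ".1.", as.integer(Sys.time()) %% 100000000L)
  for (s in seq_len(d[1])) {
    sop_uid <- paste0(series_uid, ".", s)
    z <- (s - 1) * stack$slice_thickness_mm
    stored <- round((t(stack$voxels[s, , ]) - intercept) / slope)
    if (any(stored < -32768 | stored > 32767)) {
      stopf("HU values out of range for 16-bit signed DICOM storage")
    }
    pix <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
      dcm_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE)
    )
    dataset <- c(
      dcm_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(s)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(c(0, 0, z))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]),
      dcm_element(0x0028, 0x0011, "US", d[3]),
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(stack$pixel_spacing_mm)),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(stack$slice_thickness_mm)),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", dcm_ds(intercept)),
      dcm_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta))), meta)
    file_bytes <- c(raw(128L), charToRaw("DICM"), meta, dataset)
    writeBin(file_bytes, file.path(path, sprintf("slice_%04d.dcm", s)))
  }
  invisible(path)
}

# Parse one explicit-VR LE DICOM file into the tag subset we care about.
parse_dicom_file <- function(file) {
  bytes <- readBin(file, raw(), n = file.info(file)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stopf("not a DICOM part-10 file: %s", file)
  }
  pos <- 133L
  n <- length(bytes)
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) {
    as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
      65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
  }
  tags <- list()
  transfer_syntax <- NULL
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stopf("unsupported (implicit-VR or corrupt) DICOM encoding in %s", file)
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      start <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      start <- pos + 8L
    }
    if (len == 4294967295) stopf("undefined-length elements unsupported: %s", file)
    val <- if (len > 0) bytes[start:(start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, bytes = val)
    if (key == "0002,0010") transfer_syntax <- trimws(rawToChar(val[val != as.raw(0)]))
    pos <- start + len
  }
  if (!is.null(transfer_syntax) && transfer_syntax != UID_EXPLICIT_VR_LE) {
    stopf("unsupported transfer syntax '%s' in %s", transfer_syntax, file)
  }
  tags
}

dcm_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))
}

dcm_nums <- function(tags, key) {
  s <- dcm_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_u16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  as.integer(el$bytes[1]) + 256L * as.integer(el$bytes[2])
}

read_dicom_series <- function(path) {
  if (!dir.exists(path)) stopf("DICOM directory does not exist: %s", path)
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) stopf("no DICOM files found in %s", path)
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    rows <- dcm_u16(tags, "0028,0010")
    cols <- dcm_u16(tags, "0028,0011")
    spacing <- dcm_nums(tags, "0028,0030")
    slope <- dcm_nums(tags, "0028,1053")
    intercept <- dcm_nums(tags, "0028,1052")
    if (is.null(slope) || is.null(intercept)) {
      stopf("missing RescaleSlope/RescaleIntercept in %s", f)
    }
    if (is.null(rows) || is.null(cols) || is.null(spacing)) {
      stopf("missing Rows/Columns/PixelSpacing in %s", f)
    }
    ipp <- dcm_nums(tags, "0020,0032") %||% c(0, 0, 0)
    thick <- dcm_nums(tags, "0018,0050") %||% 1
    signed <- (dcm_u16(tags, "0028,0103") %||% 1L) == 1L
    pix_el <- tags[["7FE0,0010"]]
    if (is.null(pix_el)) stopf("missing PixelData in %s", f)
    stored <- readBin(pix_el$bytes, integer(), n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    if (length(stored) != rows * cols) stopf("truncated PixelData in %s", f)
    hu <- t(matrix(stored * slope + intercept, nrow = cols))
    list(hu = hu, rows = rows, cols = cols, spacing = spacing,
         z = ipp[3], thickness = thick)
  })
  spac <- t(vapply(slices, function(s) s$spacing, numeric(2)))
  if (nrow(unique(round(spac, 8))) != 1L) {
    stopf("DICOM series has mixed pixel spacings")
  }
  dims <- t(vapply(slices, function(s) c(s$rows, s$cols), integer(2)))
  if (nrow(unique(dims)) != 1L) stopf("DICOM series has mixed matrix sizes")
  ord <- order(vapply(slices, function(s) s$z, 0))
  slices <- slices[ord]
  vox <- array(NA_real_, c(length(slices), slices[[1]]$rows, slices[[1]]$cols))
  for (s in seq_along(slices)) vox[s, , ] <- slices[[s]]$hu
  image_stack(vox, pixel_spacing_mm = slices[[1]]$spacing,
              slice_thickness_mm = slices[[1]]$thickness)
}
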