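make_stack <- function(ns = 3, nr = 80, nc = 96) {
  set.seed(4)
  image_stack(array(rnorm(ns * nr * nc, sd = 30), c(ns, nr, nc)),
              pixel_spacing_mm = c(0.5, 0.6), slice_thickness_mm = 2)
}

test_that("raw_stack round-trips voxels, spacing and header metadata", {
  st <- make_stack()
  p <- file.path(tempdir(), "rawtest")
  write_stack(st, p, "raw_stack")
  st2 <- read_stack(p, "raw_stack")
  expect_lt(max(abs(st2$voxels - st$voxels)), 1e-4)  # float32 quantisation
  expect_equal(st2$pixel_spacing_mm, st$pixel_spacing_mm)
  expect_equal(st2$slice_thickness_mm, st$slice_thickness_mm)
  hdr <- readLines(paste0(p, ".hdr"))
  expect_true(any(grepl("^n_slices: 3$", hdr)))
  expect_true(any(grepl("^n_rows: 80$", hdr)))
  expect_true(any(grepl("^n_cols: 96$", hdr)))
})

test_that("non-finite voxels are refused at write time", {
  st <- make_stack(ns = 1)
  st$voxels[1, 2, 3] <- NaN
  expect_error(write_stack(st, tempfile(), "raw_stack"), "non-finite")
})

test_that("DICOM series round-trips HU within rescale quantisation", {
  st <- make_stack()
  d <- file.path(tempdir(), "dcm_rt")
  write_stack(st, d, "dicom_series")
  expect_length(list.files(d, pattern = "\\.dcm$"), 3L)
  st2 <- read_stack(d, "dicom_series")
  expect_lt(max(abs(st2$voxels - st$voxels)), 0.5 + 1e-9)
  expect_equal(st2$pixel_spacing_mm, st$pixel_spacing_mm)
  expect_equal(st2$slice_thickness_mm, st$slice_thickness_mm)
})

test_that("an independent DICOM reader agrees on geometry and rescaled values", {
  st <- make_stack(ns = 1, nr = 32, nc = 48)
  st$voxels[] <- round(st$voxels)
  d <- file.path(tempdir(), "dcm_py")
  write_stack(st, d, "dicom_series")
  f <- list.files(d, pattern = "\\.dcm$", full.names = TRUE)[1]
  script <- tempfile(fileext = ".py")
  writeLines(sprintf(paste0(
    "import pydicom\n",
    "ds = pydicom.dcmread('%s')\n",
    "arr = ds.pixel_array.astype(float) * float(ds.RescaleSlope) + ",
    "float(ds.RescaleIntercept)\n",
    "print(ds.Rows, ds.Columns, float(ds.PixelSpacing[0]), ",
    "float(ds.PixelSpacing[1]), round(float(arr.sum()), 3))"), f), script)
  out <- system2("python", script, stdout = TRUE)
  vals <- strsplit(trimws(out[length(out)]), " ")[[1]]
  expect_equal(as.numeric(vals[1:4]), c(32, 48, 0.5, 0.6))
  expect_equal(as.numeric(vals[5]), sum(st$voxels), tolerance = 1e-6)
})

test_that("malformed series are rejected with informative errors", {
  expect_error(read_stack(file.path(tempdir(), "does_not_exist_dir"),
                          "dicom_series"), "exist")
  empty <- file.path(tempdir(), "dcm_empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(read_stack(empty, "dicom_series"), "no DICOM files")

  # mixed pixel spacings across one directory
  a <- make_stack(ns = 2, nr = 32, nc = 32)
  d <- file.path(tempdir(), "dcm_mixed")
  write_stack(a, d, "dicom_series")
  b <- image_stack(array(0, c(1, 32, 32)), pixel_spacing_mm = 0.7)
  d2 <- file.path(tempdir(), "dcm_other")
  write_stack(b, d2, "dicom_series")
  file.copy(file.path(d2, "slice_0001.dcm"), file.path(d, "slice_9999.dcm"))
  expect_error(read_stack(d, "dicom_series"), "mixed")

  # a file without rescale tags names itself in the error
  norescale <- file.path(tempdir(), "dcm_norescale")
  dir.create(norescale, showWarnings = FALSE)
  el <- function(...) cbctiq:::dcm_element(...)
  meta <- c(el(0x0002, 0x0010, "UI", cbctiq:::UID_EXPLICIT_VR_LE))
  meta <- c(el(0x0002, 0x0000, "UL", cbctiq:::uint32_le(length(meta))), meta)
  body <- c(el(0x0028, 0x0010, "US", 2L), el(0x0028, 0x0011, "US", 2L),
            el(0x0028, 0x0030, "DS", "1\\1"),
            el(0x7FE0, 0x0010, "OW", as.raw(rep(0, 8))))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body),
           file.path(norescale, "bad.dcm"))
  expect_error(read_stack(norescale, "dicom_series"), "Rescale.*bad\\.dcm")
})

test_that("slices are ordered by position regardless of file name order", {
  st <- make_stack(ns = 4, nr = 32, nc = 32)
  d <- file.path(tempdir(), "dcm_order")
  write_stack(st, d, "dicom_series")
  # shuffle names: swap first and last files
  f <- list.files(d, full.names = TRUE)
  tmp <- file.path(d, "zzz.dcm")
  file.rename(f[1], tmp)
  st2 <- read_stack(d, "dicom_series")
  expect_lt(max(abs(st2$voxels - st$voxels)), 0.5 + 1e-9)
})
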