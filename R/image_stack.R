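#' Image stack container
#'
#' The universal input of all analysis modules: a 3D array of Hounsfield-unit
#' voxels with spatial calibration. Axial slices are stored along the first
#' array dimension so `stack$voxels[s, , ]` is the s-th slice (row, col).
#' In-plane coordinates follow a fixed convention shared by every module:
#' 0-based (row, col) indices with pixel centres at integer coordinates, so the
#' physical position of a pixel is `col * pixel_spacing_mm[2]` /
#' `row * pixel_spacing_mm[1]` millimetres.
#'
#' @param voxels 3D numeric array, dimensions (slice, row, col). A matrix is
#'   promoted to a single-slice stack.
#' @param pixel_spacing_mm in-plane spacing in mm, length 2 (row, col) or a
#'   scalar used for both.
#' @param slice_thickness_mm per-slice extent in mm (default 1.991, a common
#'   CBCT reconstruction thickness).
#' @param meta free-form named list: mode name, reconstruction label,
#'   acquisition parameters, ground-truth fields for synthetic stacks.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_spacing_mm, slice_thickness_mm = 1.991,
                        meta = list()) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stopf("'voxels' must be a 3D array (slice, row, col)")
  }
  if (!all(is.finite(voxels))) stopf("voxel values must all be finite")
  if (length(pixel_spacing_mm) == 1L) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  }
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0)) {
    stopf("'pixel_spacing_mm' must be 1 or 2 strictly positive values")
  }
  if (!is.numeric(slice_thickness_mm) || length(slice_thickness_mm) != 1L ||
      !is.finite(slice_thickness_mm) || slice_thickness_mm <= 0) {
    stopf("'slice_thickness_mm' must be a single positive number")
  }
  structure(
    list(voxels = voxels,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         meta = meta),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slice(s) of %d x %d px, spacing %.4g x %.4g mm, thickness %.4g mm\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm))
  cat(sprintf("  HU range [%.1f, %.1f]", min(x$voxels), max(x$voxels)))
  if (length(x$meta)) cat(";", length(x$meta), "meta field(s)")
  cat("\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[1]

# Analysis modules require a minimum in-plane extent.
check_analysis_dims <- function(stack, min_px = 64L) {
  d <- dim(stack$voxels)
  if (d[2] < min_px || d[3] < min_px) {
    stopf("image in-plane dimensions must be at least %d px for analysis (got %d x %d)",
          min_px, d[2], d[3])
  }
  invisible(stack)
}

#' Acquisition protocol metadata
#'
#' Light record of the acquisition parameters of one CBCT mode (tube voltage,
#' tube current, exposure time, CTDIvol, field of view) and the reconstruction
#' label. Carried through reports as metadata only; no dose computation is
#' performed.
#'
#' @param mode_name character label, e.g. "head".
#' @param kV,mA,exposure_time_s,ctdi_vol_mGy numeric acquisition parameters
#'   (optional, `NA` if unknown).
#' @param fov_mm reconstructed field of view in mm (> 0).
#' @param reconstruction one of `"FBP"` or `"IR"`.
#' @return An object of class `protocol_meta`.
#' @export
protocol_meta <- function(mode_name, kV = NA_real_, mA = NA_real_,
                          exposure_time_s = NA_real_, ctdi_vol_mGy = NA_real_,
                          fov_mm, reconstruction = c("FBP", "IR")) {
  reconstruction <- match.arg(reconstruction)
  if (!is.numeric(fov_mm) || length(fov_mm) != 1L || !is.finite(fov_mm) ||
      fov_mm <= 0) {
    stopf("'fov_mm' must be a single positive number")
  }
  structure(
    list(mode_name = as.character(mode_name), kV = kV, mA = mA,
         exposure_time_s = exposure_time_s, ctdi_vol_mGy = ctdi_vol_mGy,
         fov_mm = fov_mm, reconstruction = reconstruction),
    class = "protocol_meta"
  )
}
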