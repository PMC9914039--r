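#' Square ROI specification for NPS estimation
#'
#' @param center_px length-2 (row, col) ROI centre in 0-based pixel
#'   coordinates (pixel centres at integers).
#' @param side_px square side length in pixels (>= 16).
#' @param slice_indices integer slice indices (1-based) to include; `NULL`
#'   means every slice of the stack.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_px, side_px, slice_indices = NULL) {
  if (length(center_px) != 2L) stopf("'center_px' must be length 2 (row, col)")
  side_px <- as.integer(side_px)
  if (side_px < 16L) stopf("'side_px' must be at least 16")
  structure(list(center_px = as.numeric(center_px), side_px = side_px,
                 slice_indices = slice_indices),
            class = "roi_spec")
}

# 1-based row/col index ranges of an ROI; errors if it leaves the image.
roi_indices <- function(roi, dims, label = "ROI") {
  half <- (roi$side_px - 1) / 2
  r0 <- round(roi$center_px[1] - half) + 1L
  c0 <- round(roi$center_px[2] - half) + 1L
  rows <- r0:(r0 + roi$side_px - 1L)
  cols <- c0:(c0 + roi$side_px - 1L)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > dims[2] ||
      max(cols) > dims[3]) {
    stopf("%s (centre %.1f,%.1f; side %d) lies outside the %d x %d image",
          label, roi$center_px[1], roi$center_px[2], roi$side_px,
          dims[2], dims[3])
  }
  list(rows = rows, cols = cols)
}

#' Default NPS ROI layout
#'
#' Four square ROIs at 3, 6, 9 and 12 o'clock around the image centre at the
#' phantom disk mid-radius, the standard arrangement for uniformity-module
#' noise analysis.
#'
#' @param stack an [image_stack].
#' @param side_px ROI side (82 px is typical for a ~280 mm FOV head mode,
#'   46 px for ~490 mm body modes).
#' @param radial_offset_mm distance of ROI centres from the image centre
#'   (default 50 mm, the mid-radius of a 200 mm phantom disk).
#' @return List of four [roi_spec()] objects.
#' @export
nps_roi_layout <- function(stack, side_px = 82L, radial_offset_mm = 50) {
  d <- dim(stack$voxels)
  c0 <- c((d[2] - 1) / 2, (d[3] - 1) / 2)
  off_r <- radial_offset_mm / stack$pixel_spacing_mm[1]
  off_c <- radial_offset_mm / stack$pixel_spacing_mm[2]
  lapply(list(c(0, off_c), c(off_r, 0), c(0, -off_c), c(-off_r, 0)),
         function(o) roi_spec(c0 + o, side_px))
}

#' Remove a second-order polynomial trend from an ROI
#'
#' Subtracts the least-squares 2D polynomial of total degree 2 (basis 1, x, y,
#' x^2, xy, y^2) from the ROI. Detrending is the sole low-frequency leakage
#' control of the NPS estimator: it removes means, gradients and bowl-shaped
#' offsets so the residual reflects stochastic noise.
#'
#' @param roi_pixels 2D numeric matrix of HU values, at least 3 x 3.
#' @return Residual matrix of the same dimensions; its mean is ~0 and it is
#'   orthogonal to the polynomial basis.
#' @export
detrend_roi <- function(roi_pixels) {
  if (!is.matrix(roi_pixels)) stopf("'roi_pixels' must be a matrix")
  nr <- nrow(roi_pixels); nc <- ncol(roi_pixels)
  if (nr < 3L || nc < 3L) {
    stopf("ROI must be at least 3 x 3 for a degree-2 fit (got %d x %d)", nr, nc)
  }
  X <- poly2_basis(nr, nc)
  fit <- stats::lm.fit(X, as.vector(roi_pixels))
  matrix(fit$residuals, nr, nc)
}

# Degree-2 polynomial design matrix on the pixel grid, centred for conditioning.
poly2_basis <- function(nr, nc) {
  y <- rep(seq_len(nr) - (nr + 1) / 2, times = nc)
  x <- rep(seq_len(nc) - (nc + 1) / 2, each = nr)
  cbind(1, x, y, x^2, x * y, y^2)
}

#' Two-dimensional noise power spectrum of an image stack
#'
#' Estimates the 2D NPS as
#' `NPS(fx, fy) = (dx * dy) / (Lx * Ly) * mean over ROIs of |FFT2(ROI - FIT)|^2`
#' where `FIT` is the per-ROI second-order polynomial fit ([detrend_roi()]),
#' `dx, dy` the pixel spacing and `Lx, Ly` the ROI side in pixels. The average
#' runs over every (ROI, slice) pair. The result carries DC-centred frequency
#' axes, an annularly binned radial profile, the noise magnitude
#' `sqrt(integral of NPS)` (equal to the detrended pixel standard deviation by
#' Parseval's relation) and detected radial peak frequencies.
#'
#' @param stack an [image_stack] with in-plane dimensions >= 64 px.
#' @param rois list of [roi_spec()] objects, all with the same side; `NULL`
#'   uses [nps_roi_layout()] defaults.
#' @param low_freq_cutoff peak-classification boundary passed to
#'   [find_nps_peaks()] (default 0.05 cycles/mm).
#' @return An object of class `nps_result` with fields `nps2d`, `fx`, `fy`,
#'   `radial_freq`, `radial_nps`, `noise_magnitude_hu`, `peak_freqs_mm`,
#'   `n_rois_used`, `pixel_spacing_mm`.
#' @export
compute_nps <- function(stack, rois = NULL, low_freq_cutoff = 0.05) {
  if (!inherits(stack, "image_stack")) stopf("'stack' must be an image_stack")
  check_analysis_dims(stack)
  if (is.null(rois)) rois <- nps_roi_layout(stack)
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  if (length(rois) < 1L) stopf("at least one ROI is required")
  sides <- vapply(rois, function(r) r$side_px, 0L)
  if (length(unique(sides)) != 1L) {
    stopf("all ROIs must share the same side length (got %s)",
          paste(sides, collapse = ", "))
  }
  L <- sides[1]
  d <- dim(stack$voxels)
  dx <- stack$pixel_spacing_mm[2]
  dy <- stack$pixel_spacing_mm[1]
  acc <- matrix(0, L, L)
  n_used <- 0L
  for (k in seq_along(rois)) {
    idx <- roi_indices(rois[[k]], d, label = sprintf("ROI %d", k))
    slices <- rois[[k]]$slice_indices %||% seq_len(d[1])
    for (s in slices) {
      res <- detrend_roi(stack$voxels[s, idx$rows, idx$cols])
      acc <- acc + Mod(stats::fft(res))^2
      n_used <- n_used + 1L
    }
  }
  nps2d <- fft_shift(acc * (dx * dy) / (L * L) / n_used)
  fy <- fft_shift(fft_freq(L, dy))
  fx <- fft_shift(fft_freq(L, dx))
  df <- 1 / (L * sqrt(dx * dy))  # radial bin width on the FFT grid
  fmat <- sqrt(outer(fy^2, fx^2, "+"))
  bin <- round(fmat / df)
  kmax <- floor(L / 2)
  radial <- vapply(0:kmax, function(k) {
    v <- nps2d[bin == k]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  radial_freq <- (0:kmax) * df
  keep <- !is.na(radial)
  noise_mag <- sqrt(sum(nps2d) / (L * dx) / (L * dy))
  peaks <- find_nps_peaks(radial_freq[keep], radial[keep],
                          low_freq_cutoff = low_freq_cutoff)
  structure(
    list(nps2d = nps2d, fx = fx, fy = fy,
         radial_freq = radial_freq[keep], radial_nps = radial[keep],
         noise_magnitude_hu = noise_mag, peak_freqs_mm = peaks,
         n_rois_used = n_used, pixel_spacing_mm = stack$pixel_spacing_mm),
    class = "nps_result"
  )
}

#' Detect peaks of a radial NPS profile
#'
#' Applies a 3-point moving average, then searches for local maxima, ignoring
#' the DC bin. A maximum below `low_freq_cutoff` is reported first as a
#' low-frequency (cupping-artefact) peak; the global maximum at or above the
#' cutoff is the noise-texture peak. A monotonically decreasing profile yields
#' its first interior bin, flagged with attribute `boundary = TRUE`.
#'
#' @param radial_freq increasing frequency grid (cycles/mm).
#' @param radial_nps profile values (same length, >= 5 points).
#' @param low_freq_cutoff boundary between cupping and texture peaks
#'   (default 0.05 cycles/mm).
#' @return Numeric vector of peak frequencies ordered low then high (possibly
#'   length 1), or `numeric(0)` for an all-zero profile.
#' @export
find_nps_peaks <- function(radial_freq, radial_nps, low_freq_cutoff = 0.05) {
  if (length(radial_freq) != length(radial_nps)) {
    stopf("'radial_freq' and 'radial_nps' must have equal length")
  }
  if (length(radial_nps) < 5L) stopf("profile must have at least 5 points")
  if (all(radial_nps == 0)) return(numeric(0))
  keep <- radial_freq > 0  # DC excluded from peak detection
  f <- radial_freq[keep]
  v <- radial_nps[keep]
  n <- length(v)
  sm <- v
  if (n >= 3L) sm[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  is_max <- logical(n)
  if (n >= 3L) {
    interior <- 2:(n - 1)
    is_max[interior] <- sm[interior] >= sm[interior - 1] &
      sm[interior] >= sm[interior + 1] &
      (sm[interior] > sm[interior - 1] | sm[interior] > sm[interior + 1])
  }
  boundary_first <- sm[1] > sm[2]
  if (!any(is_max)) {
    if (boundary_first) {
      return(structure(f[1], boundary = TRUE))
    }
    return(structure(f[n], boundary = TRUE))
  }
  cand <- which(is_max)
  if (boundary_first) cand <- unique(c(1L, cand))
  low <- cand[f[cand] < low_freq_cutoff]
  high <- cand[f[cand] >= low_freq_cutoff]
  peaks <- numeric(0)
  if (length(low)) peaks <- f[low[which.max(sm[low])]]
  if (length(high)) peaks <- c(peaks, f[high[which.max(sm[high])]])
  peaks
}

#' Render peak frequencies the way summary tables print them
#'
#' @param peaks numeric vector from [find_nps_peaks()].
#' @param digits rounding (default 2).
#' @return Single string such as `"0.02/0.22"`, or `""` when empty.
#' @export
format_peaks <- function(peaks, digits = 2) {
  if (!length(peaks)) return("")
  paste(formatC(round(peaks, digits), format = "fg"), collapse = "/")
}

#' @export
print.nps_result <- function(x, ...) {
  cat(sprintf("<nps_result> noise magnitude %.2f HU over %d ROI-slices\n",
              x$noise_magnitude_hu, x$n_rois_used))
  cat(sprintf("  radial profile: %d bins to %.3f /mm; peak(s): %s\n",
              length(x$radial_freq), max(x$radial_freq),
              format_peaks(x$peak_freqs_mm)))
  invisible(x)
}

#' @export
plot.nps_result <- function(x, ...) {
  graphics::plot(x$radial_freq, x$radial_nps, type = "l",
                 xlab = "spatial frequency (1/mm)",
                 ylab = expression(NPS ~ (HU^2 ~ mm^2)), ...)
  if (length(x$peak_freqs_mm)) {
    graphics::abline(v = x$peak_freqs_mm, lty = 3)
  }
  invisible(x)
}

#' Export the radial NPS profile and summary row as delimited text
#'
#' Writes `<prefix>_radial.tsv` (frequency, NPS) and `<prefix>_summary.tsv`
#' (noise magnitude, peaks, number of ROI-slice pairs).
#'
#' @param nps an `nps_result`.
#' @param prefix output file prefix (path without extension).
#' @return Paths of the files written, invisibly.
#' @export
export_nps <- function(nps, prefix) {
  radial_file <- paste0(prefix, "_radial.tsv")
  summary_file <- paste0(prefix, "_summary.tsv")
  utils::write.table(
    data.frame(freq_mm = nps$radial_freq, nps_hu2mm2 = nps$radial_nps),
    radial_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(noise_magnitude_hu = nps$noise_magnitude_hu,
               peaks_mm = format_peaks(nps$peak_freqs_mm),
               n_rois_used = nps$n_rois_used),
    summary_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(radial_file, summary_file))
}
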