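test_that("degree-2 detrending removes exactly the polynomial subspace", {
  x <- outer(rep(1, 20), 1:24)
  y <- outer(1:20, rep(1, 24))
  roi <- 3 + 2 * x - y + 0.1 * x^2
  expect_lt(max(abs(detrend_roi(roi))), 1e-8)
  expect_lt(max(abs(detrend_roi(matrix(7, 16, 16)))), 1e-10)
  expect_error(detrend_roi(matrix(1, 1, 24)), "3 x 3")
})

test_that("detrend residual matches an independent normal-equations solution", {
  set.seed(31)
  roi <- matrix(rnorm(46 * 46, sd = 12), 46)
  res <- detrend_roi(roi)
  xs <- rep(1:46 - 23.5, each = 46)
  ys <- rep(1:46 - 23.5, times = 46)
  X <- cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  beta <- solve(t(X) %*% X, t(X) %*% as.vector(roi))
  oracle <- matrix(as.vector(roi) - X %*% beta, 46)
  expect_lt(max(abs(res - oracle)) / max(abs(oracle)), 1e-8)
})

test_that("white-noise NPS is Parseval-consistent and flat away from the detrended bins", {
  set.seed(9)
  st <- image_stack(array(rnorm(40 * 160 * 160, sd = 10), c(40, 160, 160)),
                    0.55)
  rois <- lapply(list(c(40, 40), c(40, 119), c(119, 40), c(119, 119)),
                 function(c0) roi_spec(c0, 64))
  nps <- compute_nps(st, rois)
  expect_lt(abs(nps$noise_magnitude_hu / 10 - 1), 0.03)

  # Parseval: magnitude^2 == mean residual power of the detrended ROIs
  resid_ms <- mean(vapply(seq_len(40), function(s) {
    mean(vapply(rois, function(r) {
      idx <- cbctiq:::roi_indices(r, dim(st$voxels))
      mean(detrend_roi(st$voxels[s, idx$rows, idx$cols])^2)
    }, 0))
  }, 0))
  expect_lt(abs(nps$noise_magnitude_hu^2 / resid_ms - 1), 0.005)

  # flat within 10% for bins not suppressed by the polynomial detrend
  expected <- 10^2 * 0.55^2
  sel <- nps$radial_freq >= 2 / (64 * 0.55)
  expect_lt(max(abs(nps$radial_nps[sel] / expected - 1)), 0.10)

  # noiseless constant stack
  flat <- image_stack(array(5, c(2, 160, 160)), 0.55)
  expect_equal(compute_nps(flat, rois)$noise_magnitude_hu, 0)
})

test_that("NPS obeys scale equivariance and point-reflection symmetry", {
  set.seed(12)
  st <- image_stack(array(rnorm(4 * 96 * 96, sd = 8), c(4, 96, 96)), 0.7)
  rois <- list(roi_spec(c(47.5, 47.5), 64))
  n1 <- compute_nps(st, rois)
  st2 <- st
  st2$voxels <- st$voxels * 3
  n2 <- compute_nps(st2, rois)
  expect_equal(n2$nps2d, 9 * n1$nps2d, tolerance = 1e-12)
  expect_equal(n2$noise_magnitude_hu, 3 * n1$noise_magnitude_hu,
               tolerance = 1e-12)
  # real input: NPS(-f) == NPS(f) through DC (even side length, DC at L/2+1)
  L <- 64
  g <- n1$nps2d[2:L, 2:L]
  expect_equal(g, g[rev(seq_len(L - 1)), rev(seq_len(L - 1))],
               tolerance = 1e-10)
})

test_that("ROI contracts are enforced", {
  st <- image_stack(array(0, c(1, 80, 80)), 0.5)
  expect_error(compute_nps(st, list(roi_spec(c(40, 40), 32),
                                    roi_spec(c(40, 40), 16))), "same side")
  expect_error(compute_nps(st, list(roi_spec(c(5, 5), 32))), "outside")
  expect_error(roi_spec(c(10, 10), 8), "at least 16")
  small <- image_stack(array(0, c(1, 32, 32)), 0.5)
  expect_error(compute_nps(small, list(roi_spec(c(16, 16), 16))), "at least 64")
})

test_that("peak detection separates cupping and texture peaks", {
  f <- seq(0, 0.6, by = 0.01)
  # single band-pass peak at 0.29
  v1 <- f * exp(-(f / (0.29 * sqrt(2)))^2)
  expect_equal(find_nps_peaks(f, v1), 0.29, tolerance = 1e-9)
  # low cupping bump at 0.02 plus texture peak at 0.22
  v2 <- 4 * exp(-((f - 0.02) / 0.012)^2) + 2 * exp(-((f - 0.22) / 0.08)^2)
  p <- find_nps_peaks(f, v2)
  expect_length(p, 2L)
  expect_equal(p, c(0.02, 0.22), tolerance = 0.011)
  expect_equal(format_peaks(p), "0.02/0.22")
  # monotone decreasing: first interior bin, flagged as boundary
  v3 <- exp(-f / 0.1)
  p3 <- find_nps_peaks(f, v3)
  expect_equal(as.numeric(p3), 0.01)
  expect_true(isTRUE(attr(p3, "boundary")))
  expect_identical(find_nps_peaks(f, rep(0, length(f))), numeric(0))
  expect_error(find_nps_peaks(1:3, 1:3), "at least 5")
})

test_that("a static cupping bowl leaves a low-frequency residual peak", {
  cfg <- phantom_config(matrix_size = 256, pixel_spacing_mm = 492.37 / 512,
                        n_slices = 1, cupping_amplitude_hu = 30, seed = 11)
  u <- generate_uniform_module(cfg)
  nps <- compute_nps(u, nps_roi_layout(u, side_px = 46, radial_offset_mm = 50))
  expect_length(nps$peak_freqs_mm, 1L)
  expect_lt(nps$peak_freqs_mm[1], 0.05)
  expect_gt(nps$noise_magnitude_hu, 0)
})
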