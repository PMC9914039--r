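test_that("centre refinement reaches sub-0.1 px accuracy at integer and half-pixel offsets", {
  for (off in list(c(5.2, -3.1), c(head_spacing / 2, head_spacing / 2))) {
    st <- make_insert_stack(psf_sigma_mm = 0.5, contrast_hu = 790,
                            offset_mm = off)
    gt <- insert_truth(st)
    ce <- refine_center(st, spec_for(st))
    expect_lt(max(abs(ce - c(gt$center_row_px, gt$center_col_px))), 0.1)
  }
  # negative contrast insert
  stn <- make_insert_stack(psf_sigma_mm = 0.5, contrast_hu = -1000)
  gtn <- insert_truth(stn)
  cen <- refine_center(stn, spec_for(stn))
  expect_lt(max(abs(cen - c(gtn$center_row_px, gtn$center_col_px))), 0.1)
  # uniform image: no insert to find
  flat <- image_stack(array(0, c(1, 128, 128)), head_spacing)
  expect_error(refine_center(flat, insert_spec("x", c(63.5, 63.5))),
               "not found")
})

test_that("contrast is recovered exactly without noise and within 2 HU with noise", {
  st <- make_insert_stack(psf_sigma_mm = 0, contrast_hu = -1000)
  expect_equal(measure_contrast(st, spec_for(st)), -1000, tolerance = 1e-6)
  stn <- make_insert_stack(psf_sigma_mm = 0.4, contrast_hu = 793,
                           noise = noise_model("flat", 5), n_slices = 40,
                           seed = 6)
  expect_lt(abs(measure_contrast(stn, spec_for(stn)) - 793), 2)
})

test_that("a sharp disk gives a step ESF confined to at most 2 bins", {
  st <- make_insert_stack(psf_sigma_mm = 0, contrast_hu = -1000)
  esf <- compute_esf(st, spec_for(st))
  inter <- sum(esf$hu < -50 & esf$hu > -950)
  expect_lte(inter, 2L)
  lsf <- esf_to_lsf(esf)
  expect_true(all(lsf$value >= 0))  # sign flipped for negative contrast
  expect_lte(sum(lsf$value > 0.5 * max(lsf$value)), 2L)
})

test_that("the measured ESF matches a brute-force convolution oracle within 1% of edge height", {
  st <- make_insert_stack(psf_sigma_mm = 0.5, contrast_hu = 790)
  esf <- compute_esf(st, spec_for(st))
  oracle <- 790 * oracle_blurred_disk(esf$radius_mm, 6.1, 0.5)
  expect_lt(max(abs(esf$hu - oracle)), 0.01 * 790)
})

test_that("an error-function ESF differentiates to its Gaussian LSF", {
  b <- 0.05
  r <- seq(0.025, 12, by = b)
  sig <- 0.5
  esf <- data.frame(radius_mm = r, hu = 100 * pnorm((6.1 - r) / sig))
  attr(esf, "bin_width_mm") <- b
  lsf <- esf_to_lsf(esf)
  gauss <- 100 / (sig * sqrt(2 * pi)) * exp(-(lsf$radius_mm - 6.1)^2 / (2 * sig^2))
  win <- abs(lsf$radius_mm - 6.1) < 1.5 * sig  # away from the Hann taper
  expect_lt(max(abs(lsf$value[win] - gauss[win])) / max(gauss), 0.02)
  expect_error(esf_to_lsf(within(esf, hu <- 0 * hu)), "no edge")
})

test_that("TTF of Gaussian-blurred inserts follows the closed form for all blur widths", {
  for (sig in c(0.3, 0.5, 1.0)) {
    st <- make_insert_stack(psf_sigma_mm = sig, contrast_hu = 790)
    tt <- compute_ttf(st, spec_for(st))
    f50_true <- gauss_f50(sig)
    expect_lt(abs(tt$f50_mm / f50_true - 1), 0.03)
    sel <- tt$ttf$freq_mm <= f50_true
    expect_lt(max(abs(tt$ttf$value[sel] -
                      gauss_ttf_curve(sig, tt$ttf$freq_mm[sel]))), 0.03)
    expect_equal(tt$ttf$value[1], 1)
  }
})

test_that("f50 scales inversely with blur width and is contrast-invariant", {
  f50s <- vapply(c(0.5, 1.0), function(sig) {
    st <- make_insert_stack(psf_sigma_mm = sig, contrast_hu = 790)
    compute_ttf(st, spec_for(st))$f50_mm
  }, 0)
  expect_lt(abs(f50s[1] / f50s[2] / 2 - 1), 0.05)

  st_lo <- make_insert_stack(psf_sigma_mm = 0.5, contrast_hu = 235)
  st_neg <- make_insert_stack(psf_sigma_mm = 0.5, contrast_hu = -1000)
  f_lo <- compute_ttf(st_lo, spec_for(st_lo))$f50_mm
  f_neg <- compute_ttf(st_neg, spec_for(st_neg))$f50_mm
  expect_lt(abs(f_lo / f_neg - 1), 0.01)
})

test_that("an impulse LSF yields a unit TTF with no 50% crossing", {
  lsf <- data.frame(radius_mm = seq(0.05, 2, by = 0.1),
                    value = c(rep(0, 9), 1, rep(0, 10)))
  attr(lsf, "bin_width_mm") <- 0.1
  expect_warning(tt <- lsf_to_ttf(lsf), "never falls")
  expect_true(all(abs(tt$value - 1) < 1e-9))
  expect_true(is.na(tt$f50_mm))
})
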