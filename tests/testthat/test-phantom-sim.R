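test_that("flat-spectrum noise reaches its target sigma, is zero-mean and reproducible", {
  nm <- noise_model("flat", 10)
  f1 <- synthesize_noise_field(c(512, 512), 0.55, nm, seed = 7)
  expect_lt(abs(sd(as.vector(f1)) / 10 - 1), 0.02)
  expect_lt(abs(mean(f1)), 1e-10)
  f2 <- synthesize_noise_field(c(512, 512), 0.55, nm, seed = 7)
  expect_identical(f1, f2)
  expect_identical(synthesize_noise_field(c(64, 64), 0.5,
                                          noise_model("flat", 0)),
                   matrix(0, 64, 64))
  # a 1x1 grid has only the (zeroed) DC bin: degenerate
  expect_error(synthesize_noise_field(c(1, 1), 0.5, nm), "degenerate")
})

test_that("a prescribed band-pass spectrum round-trips through the NPS estimator", {
  cfg <- phantom_config(matrix_size = 256, pixel_spacing_mm = 0.55,
                        n_slices = 24,
                        noise_model = noise_model("fbp", 20, 0.29), seed = 3)
  st <- generate_uniform_module(cfg)
  rois <- nps_roi_layout(st, side_px = 64, radial_offset_mm = 30)
  nps <- compute_nps(st, rois)
  expect_lt(abs(nps$noise_magnitude_hu / 20 - 1), 0.05)
  df <- 1 / (64 * 0.55)
  expect_lte(abs(max(nps$peak_freqs_mm) - 0.29), df + 1e-9)
})

test_that("uniform module: noiseless limit, cupping depth and determinism", {
  cfg0 <- phantom_config(matrix_size = 64, pixel_spacing_mm = 1, n_slices = 3,
                         background_hu = 12)
  u0 <- generate_uniform_module(cfg0)
  expect_true(all(u0$voxels == 12))

  cfgc <- phantom_config(matrix_size = 128, pixel_spacing_mm = 1, n_slices = 1,
                         cupping_amplitude_hu = 30, phantom_diameter_mm = 100)
  img <- generate_uniform_module(cfgc)$voxels[1, , ]
  centre <- img[64, 64]
  edge <- img[64, 8]  # outside the 100 mm disk
  expect_lt(abs(abs(centre - edge) - 30), 0.5)

  cfgn <- phantom_config(matrix_size = 64, pixel_spacing_mm = 1, n_slices = 2,
                         noise_model = noise_model("flat", 5), seed = 99)
  expect_identical(generate_uniform_module(cfgn)$voxels,
                   generate_uniform_module(cfgn)$voxels)
})

test_that("insert module: interior value, contrast linearity and geometry errors", {
  st <- make_insert_stack(psf_sigma_mm = 0, contrast_hu = -1000,
                          offset_mm = c(0, 0))
  gt <- insert_truth(st)
  ctr <- round(c(gt$center_row_px, gt$center_col_px)) + 1L
  expect_equal(st$voxels[1, ctr[1], ctr[2]], -1000)

  # linearity: scaling all contrasts scales the measured contrast (noise off)
  base <- make_insert_stack(psf_sigma_mm = 0.4, contrast_hu = 235)
  scaled <- make_insert_stack(psf_sigma_mm = 0.4, contrast_hu = 2 * 235)
  c1 <- measure_contrast(base, spec_for(base))
  c2 <- measure_contrast(scaled, spec_for(scaled))
  expect_equal(c2 / c1, 2, tolerance = 1e-10)

  overlap <- data.frame(name = c("a", "b"),
                        offset_row_mm = c(0, 5), offset_col_mm = c(0, 0),
                        diameter_mm = 12.2, contrast_hu = c(100, 200))
  expect_error(phantom_config(matrix_size = 128, pixel_spacing_mm = 0.55,
                              insert_specs = overlap), "overlap")
  outside <- data.frame(name = "far", offset_row_mm = 40, offset_col_mm = 0,
                        diameter_mm = 12.2, contrast_hu = 100)
  expect_error(phantom_config(matrix_size = 128, pixel_spacing_mm = 0.55,
                              insert_specs = outside), "fit")
})

test_that("phantom configuration can round-trip through a YAML file", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "matrix_size: 128",
    "pixel_spacing_mm: 0.55",
    "n_slices: 4",
    "background_hu: 0",
    "psf_sigma_mm: 0.47",
    "cupping_amplitude_hu: 0",
    "seed: 12",
    "noise_model:",
    "  family: fbp",
    "  target_sigma_hu: 15",
    "  peak_frequency_mm: 0.29"
  ), path)
  cfg <- read_phantom_config(path)
  expect_s3_class(cfg, "phantom_config")
  expect_equal(cfg$matrix_size, 128L)
  expect_equal(cfg$noise_model$target_sigma_hu, 15)
  expect_equal(cfg$noise_model$peak_frequency_mm, 0.29)
  st <- generate_uniform_module(cfg)
  expect_equal(dim(st$voxels), c(4L, 128L, 128L))
})
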