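test_that("percent change follows the IR-vs-FBP convention", {
  expect_equal(percent_change(40.0, 26.0), -35)
  expect_equal(round(percent_change(10.6, 8.6)), -19)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("across-insert mean change reproduces published summaries", {
  f50 <- mean_change_over_inserts(c(0.41, 0.39, 0.40, 0.39),
                                  c(0.44, 0.41, 0.42, 0.40))
  expect_equal(round(f50[["mean"]]), 5)
  expect_lt(f50[["sd"]], 2.1)
  dp <- mean_change_over_inserts(c(14.7, 2.5, 3.4, 11.8),
                                 c(22.5, 4.0, 5.3, 18.1))
  expect_equal(round(dp[["mean"]]), 56)
  expect_equal(mean_change_over_inserts(1:4, 1:4),
               c(mean = 0, sd = 0))
  expect_error(mean_change_over_inserts(1:3, 1:3), "four")
})

small_config <- function(seed = 5) {
  ins <- data.frame(name = c("air", "ldpe", "delrin", "teflon"),
                    offset_row_mm = c(20, -20, 20, -20),
                    offset_col_mm = c(20, 20, -20, -20),
                    diameter_mm = 12.2,
                    contrast_hu = c(-1000, -180, 235, 790))
  modes <- list(list(
    label = "test", fov_mm = 70.4, matrix_size = 128, roi_side_px = 32,
    roi_offset_mm = 12, inserts = ins,
    recons = list(
      FBP = list(noise_model = noise_model("fbp", 12, 0.29),
                 psf_sigma_mm = 0.47),
      IR = list(noise_model = noise_model("ir", 7.8, 0.20),
                psf_sigma_mm = 0.45))))
  assessment_config(modes, nps_slices = 20, ttf_slices = 16, seed = seed)
}

test_that("the assessment pipeline is complete, deterministic and recovers the noise prescription", {
  cfg <- small_config()
  res <- run_assessment(cfg, verbose = FALSE)
  s <- res$summary
  expect_equal(nrow(s), 2L)
  expect_setequal(s$reconstruction, c("FBP", "IR"))
  num_cols <- grep("^(noise|f50|dprime|contrast)", names(s), value = TRUE)
  expect_true(all(is.finite(as.matrix(s[num_cols]))))
  expect_length(grep("^f50_", names(s)), 4L)
  expect_length(grep("^dprime_", names(s)), 4L)

  # prescription recovery: IR sigma is 35% below FBP sigma
  expect_lt(abs(res$changes$noise_change_pct - (-35)), 3)

  res2 <- run_assessment(cfg, verbose = FALSE)
  expect_identical(res$summary, res2$summary)
})

test_that("assessment output files are written and readable", {
  out <- file.path(tempdir(), "assess_out")
  res <- run_assessment(small_config(), output_dir = out, verbose = FALSE)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "changes.csv")))
  expect_true(file.exists(file.path(out, "report.txt")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "test_FBP_nps_radial.tsv")))
  expect_true(file.exists(file.path(out, "test_IR_teflon_ttf.tsv")))
  back <- utils::read.csv(file.path(out, "summary.csv"))
  expect_equal(back$noise_magnitude_hu, res$summary$noise_magnitude_hu,
               tolerance = 1e-9)
})

test_that("the reference metrics table loads with the expected structure", {
  ref <- reference_metrics()
  expect_setequal(unique(ref$mode), c("head", "thorax", "pelvis_large"))
  expect_setequal(unique(ref$reconstruction), c("FBP", "IR"))
  expect_equal(sum(ref$metric == "f50_mm"), 24L)
  expect_equal(sum(ref$metric == "contrast_hu"), 24L)
})
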