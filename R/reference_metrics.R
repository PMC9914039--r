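#' Published reference metrics for Halcyon CBCT reconstructions
#'
#' Published task-based image-quality measurements for three CBCT acquisition
#' modes (head, thorax, pelvis large) of an O-ring radiotherapy accelerator,
#' each reconstructed with filtered back projection (FBP) and iterative
#' reconstruction (IR) on a Catphan 504 phantom: noise magnitude (sqrt of the
#' NPS area, HU), radial NPS peak frequencies, per-insert TTF 50% frequencies,
#' detectability indices for matched 10 mm lesion tasks, and insert contrasts.
#' Shipped as a plain-text table; used to exercise the summary arithmetic of
#' the report module against known values.
#'
#' @return Data frame with columns `mode`, `reconstruction`, `metric`,
#'   `insert`, `value`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv", package = "cbctiq",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

ref_value <- function(ref, mode, recon, metric, insert = NA) {
  sel <- ref$mode == mode & ref$reconstruction == recon & ref$metric == metric
  ins_sel <- if (is.na(insert)) is.na(ref$insert) | ref$insert == "" else
    !is.na(ref$insert) & ref$insert == insert
  sel <- sel & ins_sel
  v <- ref$value[sel]
  if (length(v) != 1L) {
    stopf("reference lookup (%s, %s, %s, %s) matched %d rows",
          mode, recon, metric, insert, length(v))
  }
  v
}

#' Derived summary statistics of the reference metrics
#'
#' Recomputes, with [percent_change()] and [mean_change_over_inserts()], the
#' derived IR-vs-FBP summary statistics implied by [reference_metrics()]:
#' per-mode percent noise reduction, across-insert mean (+/- SD) percent
#' change of the TTF 50% frequency and of the detectability index, and the
#' across-measurement mean contrast of each insert.
#'
#' @return List with data frames `per_mode` (columns `mode`,
#'   `noise_change_pct`, `f50_change_mean_pct`, `f50_change_sd_pct`,
#'   `dprime_change_mean_pct`, `dprime_change_sd_pct`) and `contrast`
#'   (columns `insert`, `mean_hu`, `sd_hu`).
#' @export
reference_summary_stats <- function() {
  ref <- reference_metrics()
  inserts <- c("air", "ldpe", "delrin", "teflon")
  per_mode <- do.call(rbind, lapply(unique(ref$mode), function(mode) {
    noise <- percent_change(
      ref_value(ref, mode, "FBP", "noise_magnitude_hu"),
      ref_value(ref, mode, "IR", "noise_magnitude_hu"))
    f50 <- mean_change_over_inserts(
      vapply(inserts, function(i) ref_value(ref, mode, "FBP", "f50_mm", i), 0),
      vapply(inserts, function(i) ref_value(ref, mode, "IR", "f50_mm", i), 0))
    dp <- mean_change_over_inserts(
      vapply(inserts, function(i) ref_value(ref, mode, "FBP", "dprime", i), 0),
      vapply(inserts, function(i) ref_value(ref, mode, "IR", "dprime", i), 0))
    data.frame(mode = mode, noise_change_pct = noise,
               f50_change_mean_pct = f50[["mean"]],
               f50_change_sd_pct = f50[["sd"]],
               dprime_change_mean_pct = dp[["mean"]],
               dprime_change_sd_pct = dp[["sd"]],
               stringsAsFactors = FALSE)
  }))
  contrast <- do.call(rbind, lapply(inserts, function(ins) {
    v <- ref$value[ref$metric == "contrast_hu" & ref$insert == ins]
    data.frame(insert = ins, mean_hu = mean(v), sd_hu = stats::sd(v),
               stringsAsFactors = FALSE)
  }))
  list(per_mode = per_mode, contrast = contrast)
}
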