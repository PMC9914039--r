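#' Percent change between two reconstructions
#'
#' `100 * (ir - fbp) / fbp`, the convention used when reporting iterative
#' reconstruction relative to filtered back projection. Values are kept at
#' full precision; rounding to integers happens only at presentation.
#'
#' @param fbp_value,ir_value numeric vectors (recycled); `fbp_value` must be
#'   non-zero.
#' @return Percent change(s).
#' @export
percent_change <- function(fbp_value, ir_value) {
  if (any(fbp_value == 0, na.rm = TRUE)) {
    stopf("percent change undefined for a zero baseline")
  }
  100 * (ir_value - fbp_value) / fbp_value
}

#' Mean and spread of per-insert percent changes
#'
#' Computes the per-insert percent change for the four paired insert (or task)
#' metrics and returns their mean and sample (n-1) standard deviation — the
#' "mean +/- SD over the four inserts" summary of comparison tables.
#'
#' @param values_fbp,values_ir numeric vectors of exactly four paired values.
#' @return Named numeric vector `c(mean, sd)` in percent.
#' @export
mean_change_over_inserts <- function(values_fbp, values_ir) {
  if (length(values_fbp) != 4L || length(values_ir) != 4L) {
    stopf("exactly four paired insert values are required")
  }
  pc <- percent_change(values_fbp, values_ir)
  c(mean = mean(pc), sd = stats::sd(pc))
}

#' Assessment configuration
#'
#' Describes the full study: a list of acquisition modes, each with one or
#' more reconstructions whose stacks are either generated synthetically (from
#' a noise model, PSF width and cupping amplitude) or loaded from disk, plus
#' the shared insert layout, detection tasks and viewing conditions.
#'
#' Each element of `modes` is a list with fields:
#' `label` (unique mode name), `fov_mm`, `matrix_size` (default 512),
#' `roi_side_px` (NPS ROI side, default 82), `roi_offset_mm` (default 50),
#' `inserts` (data frame as in [default_inserts()]; default that layout) and
#' `recons`: a named list (`FBP`, `IR`, ...) whose entries are lists with
#' either `noise_model` (a [noise_model()]) plus optional `psf_sigma_mm` and
#' `cupping_amplitude_hu`, or `uniform_path`/`insert_path` +
#' `format` pointing at stacks readable by [read_stack()].
#'
#' @param modes list of mode descriptions (above).
#' @param view a [viewing_conditions()].
#' @param task_diameter_mm lesion diameter of the detection tasks
#'   (default 10 mm).
#' @param nps_slices slices in each uniformity stack (default 85,
#'   i.e. 17 x 5 acquisitions).
#' @param ttf_slices slices in each insert stack (default 40, i.e. 8 x 5).
#' @param background_hu phantom background level (default 0).
#' @param seed base seed; each (mode, reconstruction, module) stack derives a
#'   distinct sub-seed from it.
#' @return An object of class `assessment_config`.
#' @export
assessment_config <- function(modes, view = viewing_conditions(),
                              task_diameter_mm = 10, nps_slices = 85L,
                              ttf_slices = 40L, background_hu = 0,
                              seed = 1L) {
  if (!length(modes)) stopf("at least one mode is required")
  labels <- vapply(modes, function(m) m$label %||% "", "")
  if (any(labels == "") || anyDuplicated(labels)) {
    stopf("every mode needs a unique non-empty 'label'")
  }
  for (m in modes) {
    if (is.null(m$recons) || is.null(names(m$recons)) ||
        anyDuplicated(names(m$recons))) {
      stopf("mode '%s' needs a named list of reconstructions", m$label)
    }
  }
  structure(
    list(modes = modes, view = view, task_diameter_mm = task_diameter_mm,
         nps_slices = as.integer(nps_slices),
         ttf_slices = as.integer(ttf_slices),
         background_hu = background_hu, seed = as.integer(seed)),
    class = "assessment_config"
  )
}

# Resolve or synthesize the (uniform, insert) stack pair of one
# mode x reconstruction cell.
resolve_stacks <- function(config, mode, recon_label, sub_seed) {
  rc <- mode$recons[[recon_label]]
  if (!is.null(rc$uniform_path) || !is.null(rc$insert_path)) {
    if (is.null(rc$uniform_path) || is.null(rc$insert_path)) {
      stopf("mode '%s' / '%s': both uniform_path and insert_path are required",
            mode$label, recon_label)
    }
    fmt <- rc$format %||% "raw_stack"
    return(list(uniform = read_stack(rc$uniform_path, fmt),
                insert = read_stack(rc$insert_path, fmt)))
  }
  if (is.null(rc$noise_model)) {
    stopf("mode '%s' / '%s': provide either stack paths or a noise_model",
          mode$label, recon_label)
  }
  msize <- mode$matrix_size %||% 512L
  spacing <- mode$fov_mm / msize
  inserts <- mode$inserts %||% default_inserts()
  ucfg <- phantom_config(matrix_size = msize, pixel_spacing_mm = spacing,
                         n_slices = config$nps_slices,
                         background_hu = config$background_hu,
                         noise_model = rc$noise_model,
                         psf_sigma_mm = rc$psf_sigma_mm %||% 0,
                         cupping_amplitude_hu = rc$cupping_amplitude_hu %||% 0,
                         seed = sub_seed)
  icfg <- phantom_config(matrix_size = msize, pixel_spacing_mm = spacing,
                         n_slices = config$ttf_slices,
                         background_hu = config$background_hu,
                         insert_specs = inserts,
                         noise_model = rc$noise_model,
                         psf_sigma_mm = rc$psf_sigma_mm %||% 0,
                         cupping_amplitude_hu = rc$cupping_amplitude_hu %||% 0,
                         seed = sub_seed + 1L)
  list(uniform = generate_uniform_module(ucfg),
       insert = generate_insert_module(icfg))
}

#' Run the full task-based assessment
#'
#' For every (mode, reconstruction) pair: obtains the uniformity and insert
#' stacks (synthetic or from disk), estimates the NPS on the uniform stack,
#' measures TTF and contrast for every insert, and computes the NPWE
#' detectability index for one lesion task per insert (lesion contrast = the
#' measured insert contrast). When both an `FBP` and an `IR` reconstruction
#' are present for a mode, percent-change summaries (noise magnitude,
#' per-insert f50 and d' with across-insert mean +/- SD) are added.
#'
#' @param config an [assessment_config()].
#' @param output_dir optional directory; when given, writes `summary.csv`
#'   (full precision), `changes.csv`, a rounded human-readable `report.txt`,
#'   per-cell radial NPS / TTF curve files and a `manifest.txt` run log.
#' @param verbose print progress (default `TRUE`).
#' @return An object of class `assessment_result`: list with `summary` and
#'   `changes` data frames and a `curves` list.
#' @export
run_assessment <- function(config, output_dir = NULL, verbose = TRUE) {
  if (!inherits(config, "assessment_config")) {
    stopf("'config' must be an assessment_config")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  curves <- list()
  for (im in seq_along(config$modes)) {
    mode <- config$modes[[im]]
    for (ir in seq_along(mode$recons)) {
      recon <- names(mode$recons)[ir]
      say("mode '%s', reconstruction '%s': generating stacks", mode$label, recon)
      sub_seed <- config$seed + 1000L * im + 10L * ir
      stacks <- resolve_stacks(config, mode, recon, sub_seed)
      say("  estimating NPS (%d slices)", n_slices(stacks$uniform))
      rois <- nps_roi_layout(stacks$uniform,
                             side_px = mode$roi_side_px %||% 82L,
                             radial_offset_mm = mode$roi_offset_mm %||% 50)
      nps <- compute_nps(stacks$uniform, rois)
      inserts <- stacks$insert$meta$ground_truth$inserts %||%
        locate_inserts(stacks$insert, mode$inserts %||% default_inserts())
      row <- list(mode = mode$label, reconstruction = recon,
                  noise_magnitude_hu = nps$noise_magnitude_hu,
                  f_peak_mm = format_peaks(nps$peak_freqs_mm))
      key <- paste(mode$label, recon, sep = "_")
      curves[[key]] <- list(nps = nps, ttf = list())
      for (k in seq_len(nrow(inserts))) {
        ins <- inserts[k, ]
        say("  TTF for insert '%s'", ins$name)
        spec <- insert_spec(ins$name,
                            c(ins$center_row_px, ins$center_col_px),
                            insert_diameter_mm = ins$diameter_mm)
        tt <- compute_ttf(stacks$insert, spec)
        task <- task_spec(config$task_diameter_mm, tt$contrast_hu)
        dp <- compute_dprime(tt, nps, task, config$view)
        row[[paste0("contrast_", ins$name)]] <- tt$contrast_hu
        row[[paste0("f50_", ins$name)]] <- tt$f50_mm
        row[[paste0("dprime_", ins$name)]] <- dp$dprime
        curves[[key]]$ttf[[ins$name]] <- tt
      }
      rows[[key]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  changes <- compute_changes(summary)
  res <- structure(list(summary = summary, changes = changes, curves = curves,
                        config = config),
                   class = "assessment_result")
  if (!is.null(output_dir)) write_assessment(res, output_dir)
  res
}

# Fallback insert localisation for stacks loaded from disk: nominal layout
# centres converted to pixels around the image centre.
locate_inserts <- function(stack, inserts) {
  d <- dim(stack$voxels)
  inserts$center_row_px <- (d[2] - 1) / 2 +
    inserts$offset_row_mm / stack$pixel_spacing_mm[1]
  inserts$center_col_px <- (d[3] - 1) / 2 +
    inserts$offset_col_mm / stack$pixel_spacing_mm[2]
  inserts
}

# Percent-change block per mode (needs both FBP and IR rows).
compute_changes <- function(summary) {
  out <- list()
  metric_cols <- grep("^(f50|dprime|contrast)_", names(summary), value = TRUE)
  insert_names <- unique(sub("^(f50|dprime|contrast)_", "", metric_cols))
  for (mode in unique(summary$mode)) {
    sm <- summary[summary$mode == mode, ]
    if (!all(c("FBP", "IR") %in% sm$reconstruction)) next
    fbp <- sm[sm$reconstruction == "FBP", ]
    ir <- sm[sm$reconstruction == "IR", ]
    row <- list(mode = mode,
                noise_change_pct = percent_change(fbp$noise_magnitude_hu,
                                                  ir$noise_magnitude_hu))
    for (metric in c("f50", "dprime")) {
      cols <- paste0(metric, "_", insert_names)
      cols <- cols[cols %in% names(summary)]
      if (length(cols) == 4L) {
        mc <- mean_change_over_inserts(as.numeric(fbp[cols]),
                                       as.numeric(ir[cols]))
        row[[paste0(metric, "_change_mean_pct")]] <- mc[["mean"]]
        row[[paste0(metric, "_change_sd_pct")]] <- mc[["sd"]]
      }
    }
    for (ins in insert_names) {
      col <- paste0("contrast_", ins)
      if (col %in% names(summary)) {
        row[[paste0("contrast_change_pct_", ins)]] <-
          percent_change(fbp[[col]], ir[[col]])
      }
    }
    out[[mode]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_assessment <- function(res, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  utils::write.csv(res$summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$changes)) {
    utils::write.csv(res$changes, file.path(output_dir, "changes.csv"),
                     row.names = FALSE)
  }
  for (key in names(res$curves)) {
    export_nps(res$curves[[key]]$nps, file.path(output_dir, paste0(key, "_nps")))
    for (ins in names(res$curves[[key]]$ttf)) {
      export_ttf(res$curves[[key]]$ttf[[ins]],
                 file.path(output_dir, paste0(key, "_", ins)))
    }
  }
  writeLines(format_report(res), file.path(output_dir, "report.txt"))
  manifest <- c(
    sprintf("cbctiq %s", as.character(utils::packageVersion("cbctiq"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("base seed %d", res$config$seed),
    sprintf("nps_slices %d, ttf_slices %d", res$config$nps_slices,
            res$config$ttf_slices),
    sprintf("modes: %s", paste(vapply(res$config$modes, `[[`, "", "label"),
                               collapse = ", ")))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

# Human-readable report: percent values rounded to integers, matching the
# usual presentation of comparison tables; full precision stays in the CSVs.
format_report <- function(res) {
  lines <- c("Task-based image quality assessment", "")
  s <- res$summary
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("%s / %s:", s$mode[i], s$reconstruction[i]),
               sprintf("  noise magnitude %.1f HU, NPS peak(s) %s /mm",
                       s$noise_magnitude_hu[i], s$f_peak_mm[i]))
    for (col in grep("^f50_", names(s), value = TRUE)) {
      ins <- sub("^f50_", "", col)
      lines <- c(lines, sprintf("  %s: contrast %.1f HU, f50 %.2f /mm, d' %.1f",
                                ins, s[[paste0("contrast_", ins)]][i],
                                s[[col]][i], s[[paste0("dprime_", ins)]][i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(res$changes)) {
    lines <- c(lines, "IR vs FBP percent changes:")
    ch <- res$changes
    for (i in seq_len(nrow(ch))) {
      lines <- c(lines, sprintf(
        "  %s: noise %d%%; f50 %d +/- %d%%; d' %d +/- %d%%",
        ch$mode[i], round(ch$noise_change_pct[i]),
        round(ch$f50_change_mean_pct[i]), round(ch$f50_change_sd_pct[i]),
        round(ch$dprime_change_mean_pct[i]), round(ch$dprime_change_sd_pct[i])))
    }
  }
  lines
}

#' @export
print.assessment_result <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Read an assessment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [assessment_config()] (`view`,
#' `task_diameter_mm`, `nps_slices`, `ttf_slices`, `background_hu`, `seed`)
#' plus `modes`: a sequence of mappings with `label`, `fov_mm`,
#' `matrix_size`, `roi_side_px`, `roi_offset_mm` and `recons`, a mapping from
#' reconstruction label to either a synthetic prescription (`noise_model`
#' with `family` / `target_sigma_hu` / `peak_frequency_mm`, plus optional
#' `psf_sigma_mm`, `cupping_amplitude_hu`) or stack paths (`uniform_path`,
#' `insert_path`, `format`).
#'
#' @param path YAML file path.
#' @return An [assessment_config()].
#' @export
read_assessment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$modes)) stopf("assessment YAML needs a 'modes' sequence")
  modes <- lapply(y$modes, function(m) {
    m$recons <- lapply(m$recons, function(rc) {
      if (!is.null(rc$noise_model)) {
        rc$noise_model <- noise_model(
          family = rc$noise_model$family %||% "fbp",
          target_sigma_hu = rc$noise_model$target_sigma_hu,
          peak_frequency_mm = rc$noise_model$peak_frequency_mm)
      }
      rc
    })
    if (!is.null(m$inserts)) {
      m$inserts <- do.call(rbind, lapply(m$inserts, as.data.frame))
    }
    m
  })
  view <- viewing_conditions(
    distance_mm = y$view$distance_mm %||% 500,
    zoom = y$view$zoom %||% 1.5,
    display_pixel_pitch_mm = y$view$display_pixel_pitch_mm %||% 0.2,
    eye_exponent = y$view$eye_exponent %||% 1.3,
    eye_peak_cyc_per_deg = y$view$eye_peak_cyc_per_deg %||% 4)
  assessment_config(modes, view = view,
                    task_diameter_mm = y$task_diameter_mm %||% 10,
                    nps_slices = y$nps_slices %||% 85L,
                    ttf_slices = y$ttf_slices %||% 40L,
                    background_hu = y$background_hu %||% 0,
                    seed = y$seed %||% 1L)
}
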