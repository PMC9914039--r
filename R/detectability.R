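#' Circular lesion detection task
#'
#' The task is the discrimination of a flat (top-hat) disk lesion of given
#' diameter and signed HU contrast against a uniform background.
#'
#' @param lesion_diameter_mm lesion diameter (default 10 mm).
#' @param contrast_hu signed contrast amplitude of the present-vs-absent
#'   difference (non-zero).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(lesion_diameter_mm = 10, contrast_hu) {
  if (lesion_diameter_mm <= 0) stopf("'lesion_diameter_mm' must be positive")
  if (!is.numeric(contrast_hu) || length(contrast_hu) != 1L ||
      contrast_hu == 0) {
    stopf("'contrast_hu' must be a single non-zero number")
  }
  structure(list(lesion_diameter_mm = lesion_diameter_mm,
                 contrast_hu = contrast_hu),
            class = "task_spec")
}

#' Display and observer geometry for the NPWE model
#'
#' @param distance_mm viewing distance (default 500 mm).
#' @param zoom display zoom factor (default 1.5).
#' @param display_pixel_pitch_mm physical pitch of a display pixel
#'   (default 0.2 mm).
#' @param eye_exponent exponent n of the visual response function
#'   (default 1.3).
#' @param eye_peak_cyc_per_deg angular frequency at which the eye filter peaks
#'   (default 4 cycles/degree).
#' @return An object of class `viewing_conditions`.
#' @export
viewing_conditions <- function(distance_mm = 500, zoom = 1.5,
                               display_pixel_pitch_mm = 0.2,
                               eye_exponent = 1.3, eye_peak_cyc_per_deg = 4) {
  vals <- c(distance_mm, zoom, display_pixel_pitch_mm, eye_exponent,
            eye_peak_cyc_per_deg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("all viewing-condition parameters must be positive")
  }
  structure(list(distance_mm = distance_mm, zoom = zoom,
                 display_pixel_pitch_mm = display_pixel_pitch_mm,
                 eye_exponent = eye_exponent,
                 eye_peak_cyc_per_deg = eye_peak_cyc_per_deg),
            class = "viewing_conditions")
}

#' Task function W(u, v) of a flat disk lesion
#'
#' Analytic Fourier transform of a flat disk of radius r and contrast C:
#' `|W(rho)| = |C| * pi * r^2 * |2 J1(2 pi rho r) / (2 pi rho r)|` with DC
#' value `C * pi * r^2`. Evaluated in closed form (no discrete transform), so
#' the task carries no rasterisation or truncation error.
#'
#' @param task a [task_spec()].
#' @param fx,fy frequency axes (cycles/mm); W is evaluated on their outer grid.
#' @return Matrix `length(fy) x length(fx)` of signed W values (HU mm^2).
#' @export
task_function <- function(task, fx, fy = fx) {
  if (!inherits(task, "task_spec")) stopf("'task' must be a task_spec")
  r <- task$lesion_diameter_mm / 2
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  x <- 2 * pi * rho * r
  jinc <- ifelse(x == 0, 1, 2 * besselJ(x, 1) / ifelse(x == 0, 1, x))
  task$contrast_hu * pi * r^2 * jinc
}

#' Eye filter E(u, v) of the NPWE observer
#'
#' Visual response function `E(rho) = rho^n * exp(-c * rho^2)` in angular
#' frequency (cycles/degree), with `c` chosen so E peaks at
#' `eye_peak_cyc_per_deg`, normalised to a maximum of 1. Image frequencies are
#' converted to angular frequencies through the display chain: one image pixel
#' is displayed at `zoom * display_pixel_pitch` mm, so
#' `f_display = f_image * pixel_spacing / (zoom * pitch)` and
#' `rho_deg = f_display * distance * pi / 180`.
#'
#' @param view a [viewing_conditions()].
#' @param fx,fy image-frequency axes (cycles/mm).
#' @param pixel_spacing_mm in-plane pixel spacing of the image being viewed.
#' @return Matrix `length(fy) x length(fx)` of filter values in \[0, 1\].
#' @export
eye_filter <- function(view, fx, fy = fx, pixel_spacing_mm) {
  if (!inherits(view, "viewing_conditions")) {
    stopf("'view' must be viewing_conditions")
  }
  sp <- mean(pixel_spacing_mm)
  scale <- sp / (view$zoom * view$display_pixel_pitch_mm) *
    view$distance_mm * pi / 180
  rho <- sqrt(outer(fy^2, fx^2, "+")) * scale
  n <- view$eye_exponent
  cc <- n / (2 * view$eye_peak_cyc_per_deg^2)
  peak_val <- view$eye_peak_cyc_per_deg^n * exp(-n / 2)
  rho^n * exp(-cc * rho^2) / peak_val
}

#' NPWE detectability index
#'
#' Computes the non-prewhitening-with-eye-filter model-observer detectability
#' index
#' `d'^2 = [ iint W^2 TTF^2 E^2 du dv ]^2 / iint W^2 TTF^2 NPS E^4 du dv`
#' on the NPS frequency grid by the trapezoid rule. The TTF is applied
#' radially (rotational symmetry), interpolating its curve at each grid
#' radius; W is evaluated analytically ([task_function()]) and E by
#' [eye_filter()].
#'
#' @param ttf a `ttf_result`, or a data frame (`freq_mm`, `value`); pass
#'   `data.frame(freq_mm = c(0, Inf), value = c(1, 1))` for an ideal system.
#' @param nps an `nps_result` (fields `nps2d`, `fx`, `fy`,
#'   `pixel_spacing_mm`).
#' @param task a [task_spec()].
#' @param view a [viewing_conditions()], or `NULL` to disable the eye filter
#'   (E = 1).
#' @return An object of class `detectability_result` with fields `dprime`,
#'   `task`, `view`, `grid_spec`.
#' @export
compute_dprime <- function(ttf, nps, task, view = viewing_conditions()) {
  if (!inherits(task, "task_spec")) stopf("'task' must be a task_spec")
  curve <- if (inherits(ttf, "ttf_result")) ttf$ttf else ttf
  if (!all(c("freq_mm", "value") %in% names(curve))) {
    stopf("'ttf' must be a ttf_result or a data frame with freq_mm, value")
  }
  for (f in c("nps2d", "fx", "fy", "pixel_spacing_mm")) {
    if (is.null(nps[[f]])) stopf("'nps' lacks field '%s'", f)
  }
  fx <- nps$fx; fy <- nps$fy
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  finite <- is.finite(curve$freq_mm)
  ttf_r <- matrix(stats::approx(curve$freq_mm[finite], curve$value[finite],
                                xout = as.vector(rho), rule = 2)$y,
                  nrow = length(fy))
  W <- task_function(task, fx, fy)
  E <- if (is.null(view)) matrix(1, length(fy), length(fx)) else
    eye_filter(view, fx, fy, nps$pixel_spacing_mm)
  wts <- outer(trapz_weights(length(fy), diff(fy[1:2])),
               trapz_weights(length(fx), diff(fx[1:2])))
  common <- W^2 * ttf_r^2
  num <- sum(common * E^2 * wts)^2
  den <- sum(common * nps$nps2d * E^4 * wts)
  if (den <= 0) {
    stopf("degenerate input: NPS is zero wherever the task has support")
  }
  structure(
    list(dprime = sqrt(num / den), task = task, view = view,
         grid_spec = list(fx_range = range(fx), fy_range = range(fy),
                          df = c(diff(fy[1:2]), diff(fx[1:2])))),
    class = "detectability_result"
  )
}

#' @export
print.detectability_result <- function(x, ...) {
  cat(sprintf("<detectability_result> d' = %.2f (lesion %.1f mm, contrast %.0f HU)\n",
              x$dprime, x$task$lesion_diameter_mm, x$task$contrast_hu))
  invisible(x)
}
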