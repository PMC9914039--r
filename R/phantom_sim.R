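#' Parametric noise model with a prescribed radial noise power spectrum
#'
#' Describes stationary, radially symmetric image noise by a target pixel
#' standard deviation and a parametric radial NPS shape. Two texture families
#' emulate reconstruction-specific noise grain:
#'
#' * `"fbp"` — band-pass, `NPS(f) ∝ f · exp(-(f/f0)^2)`, the
#'   mid-frequency-peaked texture of ramp-filtered back projection;
#' * `"ir"` — the same band-pass family with a lower peak frequency (and,
#'   in use, a lower target sigma), emulating the coarser, smoother grain of
#'   iterative reconstruction: the spectrum is shifted to lower frequency and
#'   lower magnitude without concentrating extra power into the
#'   low-frequency band where lesion-detection tasks live;
#' * `"flat"` — white noise (constant NPS), mainly for validation.
#'
#' `f0` is set internally so the radial NPS peaks exactly at
#' `peak_frequency_mm` (`f0 = peak * sqrt(2)`). At synthesis the shape is normalised on
#' the actual frequency grid so the field variance equals `target_sigma_hu^2`.
#'
#' @param family `"fbp"`, `"ir"` or `"flat"`.
#' @param target_sigma_hu desired pixel standard deviation (HU, >= 0).
#' @param peak_frequency_mm radial frequency (cycles/mm) of the NPS maximum;
#'   defaults 0.29 for `"fbp"` and 0.20 for `"ir"`, ignored for `"flat"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(family = c("fbp", "ir", "flat"), target_sigma_hu,
                        peak_frequency_mm = NULL) {
  family <- match.arg(family)
  if (!is.numeric(target_sigma_hu) || length(target_sigma_hu) != 1L ||
      !is.finite(target_sigma_hu) || target_sigma_hu < 0) {
    stopf("'target_sigma_hu' must be a single number >= 0")
  }
  if (family == "flat") {
    peak_frequency_mm <- NA_real_
  } else {
    peak_frequency_mm <- peak_frequency_mm %||%
      switch(family, fbp = 0.29, ir = 0.20)
    if (!is.finite(peak_frequency_mm) || peak_frequency_mm <= 0) {
      stopf("'peak_frequency_mm' must be positive")
    }
  }
  structure(
    list(family = family, target_sigma_hu = target_sigma_hu,
         peak_frequency_mm = peak_frequency_mm),
    class = "noise_model"
  )
}

# Unnormalised radial NPS shape evaluated at frequencies f (cycles/mm).
nps_shape <- function(model, f) {
  switch(model$family,
         flat = { s <- f; s[] <- 1; s },
         fbp = ,
         ir = {
           f0 <- model$peak_frequency_mm * sqrt(2)
           f * exp(-(f / f0)^2)
         })
}

#' Synthesize a stationary noise field with a prescribed NPS
#'
#' Generates a zero-mean Gaussian random field whose expected 2D noise power
#' spectrum equals the model's radial shape, by Fourier-domain amplitude
#' filtering of white noise. The shape is normalised on the synthesis grid so
#' the expected pixel variance is exactly `target_sigma_hu^2`; the DC bin is
#' zeroed so the field is mean-free.
#'
#' @param shape integer length-2 grid dimensions (rows, cols).
#' @param spacing_mm isotropic pixel spacing in mm.
#' @param model a [noise_model].
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched and output is reproducible.
#' @return A `shape[1] x shape[2]` numeric matrix of HU deviations.
#' @export
synthesize_noise_field <- function(shape, spacing_mm, model, seed = NULL) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (any(shape <= 0)) stopf("'shape' must be positive")
  if (spacing_mm <= 0) stopf("'spacing_mm' must be positive")
  if (!inherits(model, "noise_model")) stopf("'model' must be a noise_model")
  nr <- shape[1]; nc <- shape[2]
  if (model$target_sigma_hu == 0) return(matrix(0, nr, nc))
  fr <- fft_freq(nr, spacing_mm)
  fc <- fft_freq(nc, spacing_mm)
  fmat <- sqrt(outer(fr^2, fc^2, "+"))
  s <- nps_shape(model, fmat)
  s[1, 1] <- 0  # enforce zero mean
  df2 <- 1 / (nr * spacing_mm) / (nc * spacing_mm)
  tot <- sum(s) * df2
  if (tot <= 0) stopf("degenerate noise model: NPS shape is zero everywhere")
  s <- s * model$target_sigma_hu^2 / tot
  w <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  X <- stats::fft(w) * sqrt(s) / spacing_mm
  Re(stats::fft(X, inverse = TRUE)) / (nr * nc)
}

#' Synthetic phantom configuration
#'
#' Full parameterisation of a synthetic Catphan-like phantom stack: matrix and
#' spacing, background level, cylindrical contrast inserts, Gaussian system
#' blur, noise model, optional cupping artefact and the random seed. A fixed
#' configuration (including seed) always produces bit-identical voxels.
#'
#' @param matrix_size pixels per side (default 512).
#' @param pixel_spacing_mm in-plane pixel spacing (mm); the default corresponds
#'   to a 281.6 mm head field of view on a 512 matrix.
#' @param slice_thickness_mm slice thickness (default 1.991 mm).
#' @param n_slices number of axial slices.
#' @param background_hu mean background level (default 0, water-like).
#' @param insert_specs data frame with columns `name`, `offset_row_mm`,
#'   `offset_col_mm` (centre offsets from the image centre), `diameter_mm`,
#'   `contrast_hu`; `NULL` for no inserts (see [default_inserts()]).
#' @param psf_sigma_mm isotropic Gaussian system blur standard deviation (mm);
#'   0 disables blur.
#' @param noise_model a [noise_model], or `NULL` for noiseless output.
#' @param cupping_amplitude_hu peak-to-centre depth (HU) of the radial bowl
#'   artefact; 0 disables it.
#' @param phantom_diameter_mm diameter of the phantom disk (default 200 mm,
#'   the Catphan 504 nominal) used by the cupping field and default layouts.
#' @param seed integer random seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = 512L, pixel_spacing_mm = 281.6 / 512,
                           slice_thickness_mm = 1.991, n_slices = 1L,
                           background_hu = 0, insert_specs = NULL,
                           psf_sigma_mm = 0, noise_model = NULL,
                           cupping_amplitude_hu = 0,
                           phantom_diameter_mm = 200, seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  if (matrix_size <= 0) stopf("'matrix_size' must be positive")
  if (pixel_spacing_mm <= 0) stopf("'pixel_spacing_mm' must be positive")
  if (n_slices <= 0) stopf("'n_slices' must be positive")
  if (!is.null(noise_model) && !inherits(noise_model, "noise_model")) {
    stopf("'noise_model' must be NULL or a noise_model")
  }
  if (cupping_amplitude_hu < 0) stopf("'cupping_amplitude_hu' must be >= 0")
  cfg <- structure(
    list(matrix_size = matrix_size, pixel_spacing_mm = pixel_spacing_mm,
         slice_thickness_mm = slice_thickness_mm,
         n_slices = as.integer(n_slices),
         background_hu = background_hu, insert_specs = insert_specs,
         psf_sigma_mm = psf_sigma_mm, noise_model = noise_model,
         cupping_amplitude_hu = cupping_amplitude_hu,
         phantom_diameter_mm = phantom_diameter_mm,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
  if (!is.null(insert_specs)) validate_inserts(cfg)
  cfg
}

#' Default sensitometry insert layout
#'
#' Four 12.2 mm cylindrical inserts (air, LDPE, Delrin, Teflon) at nominal
#' contrasts of -1000, -180, +235 and +790 HU against a 0 HU background,
#' arranged on a circle of the given radius at 45/135/225/315 degrees.
#'
#' @param circle_radius_mm radius of the insert circle (default 58.4 mm).
#' @param diameter_mm insert diameter (default 12.2 mm).
#' @return Data frame usable as `insert_specs` in [phantom_config()].
#' @export
default_inserts <- function(circle_radius_mm = 58.4, diameter_mm = 12.2) {
  ang <- (c(45, 135, 225, 315)) * pi / 180
  data.frame(
    name = c("air", "ldpe", "delrin", "teflon"),
    offset_row_mm = circle_radius_mm * sin(ang),
    offset_col_mm = circle_radius_mm * cos(ang),
    diameter_mm = diameter_mm,
    contrast_hu = c(-1000, -180, 235, 790),
    stringsAsFactors = FALSE
  )
}

validate_inserts <- function(config) {
  ins <- config$insert_specs
  need <- c("name", "offset_row_mm", "offset_col_mm", "diameter_mm",
            "contrast_hu")
  if (!is.data.frame(ins) || !all(need %in% names(ins)) || nrow(ins) == 0) {
    stopf("'insert_specs' must be a non-empty data frame with columns %s",
          paste(need, collapse = ", "))
  }
  half_extent <- (config$matrix_size - 1) / 2 * config$pixel_spacing_mm
  r <- ins$diameter_mm / 2
  d_centre <- sqrt(ins$offset_row_mm^2 + ins$offset_col_mm^2)
  if (any(d_centre + r > half_extent)) {
    stopf("insert '%s' does not fit inside the field of view",
          ins$name[which.max(d_centre + r)])
  }
  if (nrow(ins) > 1) {
    for (i in seq_len(nrow(ins) - 1)) {
      for (j in (i + 1):nrow(ins)) {
        dd <- sqrt((ins$offset_row_mm[i] - ins$offset_row_mm[j])^2 +
                   (ins$offset_col_mm[i] - ins$offset_col_mm[j])^2)
        if (dd < r[i] + r[j]) {
          stopf("inserts '%s' and '%s' overlap", ins$name[i], ins$name[j])
        }
      }
    }
  }
  invisible(config)
}

# Raised-cosine radial bowl, depth A at the phantom centre, 0 at the disk
# edge and beyond. Deliberately non-polynomial so that second-order ROI
# detrending leaves low-frequency residual power (the cupping NPS peak).
cupping_field <- function(config) {
  n <- config$matrix_size
  if (config$cupping_amplitude_hu == 0) return(matrix(0, n, n))
  sp <- config$pixel_spacing_mm
  c0 <- (n - 1) / 2 * sp
  x <- (0:(n - 1)) * sp - c0
  r <- sqrt(outer(x^2, x^2, "+"))
  R <- config$phantom_diameter_mm / 2
  rr <- pmin(r / R, 1)
  -config$cupping_amplitude_hu / 2 * (1 + cos(pi * rr))
}

# Radial profile of a unit disk of given radius convolved with an isotropic
# Gaussian, evaluated at radii r (mm). Uses the polar-coordinate integral
#   g(r) = \int_0^R s/sigma^2 exp(-(s-r)^2/(2 sigma^2)) I0e(r s / sigma^2) ds
# with the exponentially scaled Bessel I0 for numerical stability.
blurred_disk_profile <- function(r, radius, sigma) {
  if (sigma <= 0) return(as.numeric(r <= radius))
  out <- numeric(length(r))
  lo <- radius - 7 * sigma
  hi <- radius + 7 * sigma
  out[r <= lo] <- 1
  mid <- which(r > lo & r < hi)
  if (length(mid)) {
    ds <- sigma / 40
    s_grid <- seq(max(ds / 2, radius - 14 * sigma), radius, by = ds)
    rs <- r[mid]
    # outer evaluation: rows = radii, cols = integration nodes
    sm <- matrix(s_grid, nrow = length(rs), ncol = length(s_grid), byrow = TRUE)
    rm_ <- matrix(rs, nrow = length(rs), ncol = length(s_grid))
    integrand <- sm / sigma^2 * exp(-(sm - rm_)^2 / (2 * sigma^2)) *
      besselI(rm_ * sm / sigma^2, 0, expon.scaled = TRUE)
    out[mid] <- rowSums(integrand) * ds
  }
  pmin(pmax(out, 0), 1)
}

# Noiseless structural slice: background + cupping + blurred inserts.
# Pixel values are point samples of the continuous object convolved with the
# Gaussian PSF (CT pixels sample a continuous reconstruction; modelling a
# pixel aperture would fold an extra sinc MTF into every TTF measurement).
render_structure <- function(config) {
  n <- config$matrix_size
  sp <- config$pixel_spacing_mm
  base <- matrix(config$background_hu, n, n) + cupping_field(config)
  ins <- config$insert_specs
  if (is.null(ins)) return(base)
  c0 <- (n - 1) / 2 * sp
  coord <- (0:(n - 1)) * sp
  for (i in seq_len(nrow(ins))) {
    cy <- c0 + ins$offset_row_mm[i]
    cx <- c0 + ins$offset_col_mm[i]
    R <- ins$diameter_mm[i] / 2
    reach <- R + 7 * config$psf_sigma_mm + 2 * sp
    rows <- which(abs(coord - cy) <= reach)
    cols <- which(abs(coord - cx) <= reach)
    if (!length(rows) || !length(cols)) next
    rmat <- sqrt(outer((coord[rows] - cy)^2, (coord[cols] - cx)^2, "+"))
    base[rows, cols] <- base[rows, cols] +
      ins$contrast_hu[i] *
      matrix(blurred_disk_profile(as.vector(rmat), R, config$psf_sigma_mm),
             nrow = length(rows))
  }
  base
}

add_noise_slices <- function(base, config, truth_kind) {
  n <- config$matrix_size
  vox <- array(0, c(config$n_slices, n, n))
  gen <- function() {
    for (s in seq_len(config$n_slices)) {
      slice <- base
      if (!is.null(config$noise_model) &&
          config$noise_model$target_sigma_hu > 0) {
        slice <- slice + synthesize_noise_field(c(n, n),
                                                config$pixel_spacing_mm,
                                                config$noise_model)
      }
      vox[s, , ] <<- slice
    }
  }
  with_seed(config$seed, gen())
  meta <- list(kind = truth_kind, config = config,
               ground_truth = list(
                 background_hu = config$background_hu,
                 noise_sigma_hu = if (is.null(config$noise_model)) 0 else
                   config$noise_model$target_sigma_hu,
                 nps_peak_mm = if (is.null(config$noise_model)) NA_real_ else
                   config$noise_model$peak_frequency_mm,
                 psf_sigma_mm = config$psf_sigma_mm,
                 cupping_amplitude_hu = config$cupping_amplitude_hu))
  if (!is.null(config$insert_specs)) {
    ins <- config$insert_specs
    c0_px <- (config$matrix_size - 1) / 2
    ins$center_row_px <- c0_px + ins$offset_row_mm / config$pixel_spacing_mm
    ins$center_col_px <- c0_px + ins$offset_col_mm / config$pixel_spacing_mm
    meta$ground_truth$inserts <- ins
  }
  image_stack(vox, pixel_spacing_mm = config$pixel_spacing_mm,
              slice_thickness_mm = config$slice_thickness_mm, meta = meta)
}

#' Generate a synthetic uniformity module
#'
#' Emulates the uniform section of an image-quality phantom (Catphan CTP486):
#' a constant background plus optional cupping bowl, with independent
#' per-slice noise fields drawn from the configured [noise_model()]. Intended
#' as input to [compute_nps()].
#'
#' @param config a [phantom_config()]; `insert_specs` are ignored.
#' @return An [image_stack] with ground-truth fields in `meta`.
#' @export
generate_uniform_module <- function(config) {
  if (!inherits(config, "phantom_config")) stopf("'config' must be a phantom_config")
  cfg <- config
  cfg$insert_specs <- NULL
  add_noise_slices(render_structure(cfg), cfg, "uniform_module")
}

#' Generate a synthetic sensitometry (insert) module
#'
#' Emulates a multi-insert sensitometry module (Catphan CTP404): cylindrical
#' inserts of prescribed diameter and contrast on a uniform background, blurred
#' by the isotropic Gaussian system PSF, with independent per-slice noise.
#' Ground-truth contrasts and sub-pixel centres are recorded in `meta`.
#' Intended as input to [compute_ttf()].
#'
#' @param config a [phantom_config()] with non-empty, non-overlapping
#'   `insert_specs`.
#' @return An [image_stack] with ground-truth fields in `meta`.
#' @export
generate_insert_module <- function(config) {
  if (!inherits(config, "phantom_config")) stopf("'config' must be a phantom_config")
  if (is.null(config$insert_specs)) {
    stopf("'config$insert_specs' must be provided for an insert module")
  }
  validate_inserts(config)
  add_noise_slices(render_structure(config), config, "insert_module")
}

#' Read a phantom configuration from a YAML file
#'
#' Keys mirror the arguments of [phantom_config()]; `noise_model` is a mapping
#' with keys `family`, `target_sigma_hu`, `peak_frequency_mm`, and
#' `insert_specs` a sequence of mappings with the columns of
#' [default_inserts()] (or the string `"default"`).
#'
#' @param path YAML file path.
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- NULL
  if (!is.null(y$noise_model)) {
    nm <- noise_model(family = y$noise_model$family %||% "fbp",
                      target_sigma_hu = y$noise_model$target_sigma_hu,
                      peak_frequency_mm = y$noise_model$peak_frequency_mm)
  }
  ins <- NULL
  if (!is.null(y$insert_specs)) {
    ins <- if (identical(y$insert_specs, "default")) default_inserts() else
      do.call(rbind, lapply(y$insert_specs, as.data.frame))
  }
  phantom_config(
    matrix_size = y$matrix_size %||% 512L,
    pixel_spacing_mm = y$pixel_spacing_mm %||% (281.6 / 512),
    slice_thickness_mm = y$slice_thickness_mm %||% 1.991,
    n_slices = y$n_slices %||% 1L,
    background_hu = y$background_hu %||% 0,
    insert_specs = ins,
    psf_sigma_mm = y$psf_sigma_mm %||% 0,
    noise_model = nm,
    cupping_amplitude_hu = y$cupping_amplitude_hu %||% 0,
    phantom_diameter_mm = y$phantom_diameter_mm %||% 200,
    seed = y$seed %||% 1L
  )
}
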