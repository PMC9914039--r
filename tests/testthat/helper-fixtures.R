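# Shared fixtures: all synthetic, generated at test time.

head_spacing <- 281.6 / 512  # mm, head-mode FOV on a 512 matrix

# Single-insert phantom stack on a small matrix, with ground truth attached.
make_insert_stack <- function(psf_sigma_mm = 0, contrast_hu = 790,
                              offset_mm = c(5.2, -3.1), diameter_mm = 12.2,
                              noise = NULL, n_slices = 1L, matrix_size = 128L,
                              spacing = head_spacing, seed = 1L,
                              name = "insert") {
  ins <- data.frame(name = name, offset_row_mm = offset_mm[1],
                    offset_col_mm = offset_mm[2], diameter_mm = diameter_mm,
                    contrast_hu = contrast_hu, stringsAsFactors = FALSE)
  cfg <- phantom_config(matrix_size = matrix_size, pixel_spacing_mm = spacing,
                        n_slices = n_slices, insert_specs = ins,
                        psf_sigma_mm = psf_sigma_mm, noise_model = noise,
                        seed = seed)
  generate_insert_module(cfg)
}

insert_truth <- function(stack) stack$meta$ground_truth$inserts

spec_for <- function(stack, name = NULL) {
  gt <- insert_truth(stack)
  if (!is.null(name)) gt <- gt[gt$name == name, ]
  insert_spec(gt$name[1], c(gt$center_row_px[1], gt$center_col_px[1]),
              insert_diameter_mm = gt$diameter_mm[1])
}

# Independent oracle for the radial profile of a Gaussian-blurred disk:
# brute-force FFT convolution of a finely sampled disk indicator, evaluated
# along a row through the centre (deliberately a different route than the
# package's radial Bessel integral).
oracle_blurred_disk <- function(r, radius, sigma, h = 0.02) {
  half <- radius + 6 * sigma + 1
  x <- seq(-half, half, by = h)
  n <- length(x)
  disk <- (outer(x^2, x^2, "+") <= radius^2) * 1
  fr <- c(0:(ceiling(n / 2) - 1), -(n - ceiling(n / 2)):-1) / (n * h)
  G <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fr^2, "+"))
  blur <- Re(stats::fft(stats::fft(disk) * G, inverse = TRUE)) / n^2
  mid <- which.min(abs(x))
  stats::approx(x[mid:n], blur[mid, mid:n], xout = r, rule = 2)$y
}

# Gaussian MTF closed forms.
gauss_ttf_curve <- function(sigma, f) exp(-2 * pi^2 * sigma^2 * f^2)
gauss_f50 <- function(sigma) sqrt(log(2) / 2) / (pi * sigma)

# DC-centred white-NPS grid for detectability closed forms.
white_nps_grid <- function(n0, n = 512L, spacing = 0.25) {
  df <- 1 / (n * spacing)
  fx <- (seq_len(n) - n / 2 - 1) * df
  list(nps2d = matrix(n0, n, n), fx = fx, fy = fx,
       pixel_spacing_mm = c(spacing, spacing))
}

ideal_ttf <- data.frame(freq_mm = c(0, 1e6), value = c(1, 1))
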