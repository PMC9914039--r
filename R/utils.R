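# Internal numeric helpers shared across modules.

# DFT sample frequencies (cycles/mm) in FFT storage order, numpy-style:
# 0, 1, ..., n/2-1, -n/2, ..., -1 over (n * spacing).
fft_freq <- function(n, spacing = 1) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * spacing)
}

# Reorder an FFT-layout vector/matrix so DC sits at the centre.
fft_shift <- function(x) {
  if (is.matrix(x)) {
    nr <- nrow(x); nc <- ncol(x)
    x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
      c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
  } else {
    n <- length(x)
    x[c((floor(n / 2) + 1):n, 1:floor(n / 2))]
  }
}

# Trapezoid quadrature weights for a uniform 1D grid of step h.
trapz_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
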