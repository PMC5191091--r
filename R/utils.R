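# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation code does not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a vector by `s` places (positive = towards larger indices), zero-fill.
shift_vec <- function(v, s, fill = 0) {
  n <- length(v)
  s <- as.integer(s)
  if (s == 0L) return(v)
  out <- rep(fill, n)
  if (s > 0L) {
    if (s < n) out[(s + 1L):n] <- v[1L:(n - s)]
  } else {
    if (-s < n) out[1L:(n + s)] <- v[(1L - s):n]
  }
  out
}

# Shift all rows of a matrix axially (rows = depth), zero-fill vacated rows.
shift_mat_rows <- function(m, s, fill = 0) {
  if (s == 0L) return(m)
  out <- matrix(fill, nrow(m), ncol(m))
  nz <- nrow(m)
  s <- as.integer(s)
  if (s > 0L) {
    if (s < nz) out[(s + 1L):nz, ] <- m[1L:(nz - s), ]
  } else {
    if (-s < nz) out[1L:(nz + s), ] <- m[(1L - s):nz, ]
  }
  out
}

# FFT of a wrapped, anisotropic Gaussian kernel normalised to unit energy
# (sum of squared weights = 1), so convolved white noise keeps unit variance.
speckle_kernel_fft <- function(nz, nx, sigma_z, sigma_x) {
  dz <- pmin(0:(nz - 1), nz - (0:(nz - 1)))
  dx <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  kz <- exp(-dz^2 / (2 * sigma_z^2))
  kx <- exp(-dx^2 / (2 * sigma_x^2))
  k <- outer(kz, kx)
  k <- k / sqrt(sum(k^2))
  stats::fft(k)
}

# Circular convolution of a real matrix with a precomputed kernel FFT.
fft_filter <- function(m, kernel_fft) {
  Re(stats::fft(stats::fft(m) * kernel_fft, inverse = TRUE)) / length(m)
}

# Moving average along a vector with a centred window (edge-truncated).
running_mean <- function(v, k) {
  if (k <= 1L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Odd-window cross-column median with edge handling, tolerant of short input.
median_smooth <- function(v, window) {
  window <- as.integer(window)
  if (window < 3L || length(v) < window) return(v)
  if (window %% 2L == 0L) window <- window + 1L
  stats::runmed(v, window, endrule = "median")
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
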