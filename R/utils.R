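#' @importFrom stats fft mvfft rnorm runif rpois rlnorm var sd median mad
#'   qt pt cor aov coef quantile approx
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage seeds, so each
#' pipeline stage owns an independent, reproducible random stream. The rule
#' is a fixed linear congruence modulo 2^31 - 1; results stay inside the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed master seed (integer).
#' @param k stage index (integer >= 0); distinct stages use distinct `k`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 100000
  as.integer(((s * 20011 + as.numeric(k) * 7919 + 1237) %% 2147483646) + 1)
}

# Polynomial rolling hash of a character vector, reported as 8 hex digits.
# Used only to stamp run reports with a config fingerprint.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Fourier-domain resampling
#'
#' Resamples a signal (or each column of a matrix) to a new rate by
#' truncating its discrete Fourier spectrum at the new Nyquist frequency
#' and inverse-transforming at the new length. The implicit anti-aliasing
#' filter is a brick wall, so content above `fs_new/2` is removed entirely
#' and in-band amplitudes are preserved. Output length is
#' `floor(n * fs_new / fs_old)`.
#'
#' @param x numeric vector or matrix (samples in rows).
#' @param fs_old,fs_new old and new sampling rates in Hz; `fs_new` may be
#'   lower (decimation) or higher (interpolation) than `fs_old`.
#' @return resampled vector or matrix with `floor(n * fs_new / fs_old)` rows.
#' @export
fft_resample <- function(x, fs_old, fs_new) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  m <- floor(n * fs_new / fs_old)
  if (m < 2) stop("resampled length would be < 2", call. = FALSE)
  if (m == n) return(if (vec) x[, 1] else x)
  X <- mvfft(x)
  Y <- matrix(0 + 0i, m, ncol(x))
  keep <- min(n, m)
  half <- (keep - 1) %/% 2                  # strictly positive bins kept
  Y[1, ] <- X[1, ]                          # DC
  if (half >= 1) {
    idx <- seq_len(half)
    Y[1 + idx, ] <- X[1 + idx, ]
    Y[m + 1 - idx, ] <- X[n + 1 - idx, ]
  }
  if (keep %% 2 == 0) {
    # shared Nyquist-edge bin: split symmetrically to keep the output real
    k <- keep %/% 2
    if (m < n) Y[k + 1, ] <- (X[k + 1, ] + X[n - k + 1, ]) / 2
    else { Y[k + 1, ] <- X[k + 1, ] / 2; Y[m - k + 1, ] <- X[k + 1, ] / 2 }
  }
  out <- Re(mvfft(Y, inverse = TRUE)) * (m / n) / m
  if (vec) out[, 1] else out
}

# Analytic signal via the one-sided FFT construction; abs() of the result
# is the instantaneous amplitude envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase Butterworth band-pass (order `order`, forward-backward).
bandpass_filtfilt <- function(x, fs, band, order = 3) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band edge at or above Nyquist", call. = FALSE)
  bf <- signal::butter(order, band / ny, type = "pass")
  signal::filtfilt(bf, x)
}

lowpass_filtfilt <- function(x, fs, cutoff, order = 2) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Great-circle distance (radians) between unit vectors: one point vs matrix,
# or all pairs of rows when `b` is missing.
gc_dist <- function(a, b = NULL) {
  if (is.null(b)) {
    g <- tcrossprod(a)
    g[] <- pmin(1, pmax(-1, g))
    return(acos(g))
  }
  d <- drop(b %*% a)
  acos(pmin(1, pmax(-1, d)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
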