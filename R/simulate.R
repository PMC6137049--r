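#' Construct an EEG recording object
#'
#' @param data numeric matrix, samples x channels, microvolts.
#' @param fs sampling rate, Hz.
#' @param layout an `eeg_layout` with one entry per column of `data`.
#' @param reference `"vertex"` or `"average"`.
#' @param quality per-channel `"good"`/`"bad"` flags.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, layout,
                          reference = c("vertex", "average"),
                          quality = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  stopifnot(inherits(layout, "eeg_layout"),
            ncol(data) == length(layout$channel_names))
  if (is.null(quality)) quality <- rep("good", ncol(data))
  stopifnot(length(quality) == ncol(data), all(quality %in% c("good", "bad")))
  colnames(data) <- layout$channel_names
  structure(list(data = data, fs = fs, layout = layout,
                 reference = reference, quality = quality),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d samples x %d channels at %g Hz (%.1f s), %s reference, %d bad\n",
    nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs, x$reference,
    sum(x$quality == "bad")))
  invisible(x)
}

# Convolve each kernel column with the envelope (FFT, linear convolution),
# truncated to the envelope length. Returns samples x channels.
convolve_kernel <- function(env_values, kernel) {
  n <- length(env_values)
  l <- nrow(kernel)
  nfft <- stats::nextn(n + l - 1, c(2, 3, 5))
  E <- fft(c(env_values, numeric(nfft - n)))
  K <- mvfft(rbind(kernel, matrix(0, nfft - l, ncol(kernel))))
  Re(mvfft(K * E, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
}

# Spatially correlated pink-ish noise: `n_src` independent sources with
# amplitude spectrum 1/sqrt(f^2 + f0^2) (1/f^2 power above f0 = 1 Hz,
# flat below, so drift stays bounded), mixed through smooth random scalp
# maps, plus a little independent sensor noise for full rank.
pink_noise_matrix <- function(n, fs, layout, n_src = 8, exponent = 2) {
  p <- length(layout$channel_names)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)
  shape <- 1 / (f_fold^2 + 1)^(exponent / 4)   # amplitude shaping
  shape[1] <- 0
  src <- matrix(rnorm(n * n_src), n, n_src)
  S <- mvfft(src) * shape
  src <- Re(mvfft(S, inverse = TRUE)) / n
  centres <- matrix(rnorm(3 * n_src), n_src, 3)
  centres <- centres / sqrt(rowSums(centres^2))
  A <- apply(centres, 1, function(cc)
    0.1 + exp(-(gc_dist(cc, layout$positions) / 0.6)^2))
  noise <- src %*% t(A)
  sensor <- matrix(rnorm(n * p), n, p)
  Ssen <- mvfft(sensor) * shape
  sensor <- Re(mvfft(Ssen, inverse = TRUE)) / n
  noise <- noise / sd(noise) + 0.25 * sensor / sd(sensor)
  noise
}

#' Simulate a multichannel EEG recording with known coupling
#'
#' Forward model: the EEG is the ground-truth kernel convolved with the
#' speech envelope, scaled by `coupling_gain`, plus spatially correlated
#' 1/f^2 background noise scaled to `snr_db` (defined against the
#' unit-coupling response, so the noise floor is register-independent),
#' plus boxcar-windowed high-variance artifact bursts on contiguous
#' channel groups, with `bad_channel_count` channels replaced outright by
#' high-variance noise and flagged bad. Data are tagged as
#' vertex-referenced: the kernel is defined directly in the recorded
#' (vertex-referenced) sensor space.
#'
#' @param envelope a [generate_envelope()] envelope (rate must equal
#'   `config$fs_eeg`; resample beforehand otherwise).
#' @param truth a [generate_kernel()] ground truth on the same layout and
#'   rate.
#' @param config a [sim_config()].
#' @param keep_parts if `TRUE`, attach the signal/noise/artifact
#'   components as `attr(, "parts")` and burst/bad-channel ground truth as
#'   `attr(, "artifacts")`.
#' @param orthogonalize if `TRUE`, project the noise (and artifacts) off
#'   the signal component channel-wise so component variances add exactly.
#' @return an `eeg_recording`; `attr(, "artifacts")` holds burst onsets,
#'   durations and channels when `keep_parts = TRUE`.
#' @export
simulate_eeg <- function(envelope, truth, config, keep_parts = FALSE,
                         orthogonalize = FALSE) {
  stopifnot(inherits(envelope, "speech_envelope"),
            inherits(truth, "trf_ground_truth"),
            inherits(config, "sim_config"))
  if (abs(envelope$fs - config$fs_eeg) > 1e-9)
    stop("envelope rate differs from fs_eeg; resample the envelope first",
         call. = FALSE)
  if (abs(truth$fs - config$fs_eeg) > 1e-9)
    stop("kernel lag grid rate differs from fs_eeg", call. = FALSE)
  layout <- truth$layout
  p <- ncol(truth$kernel)
  n <- length(envelope$values)
  fs <- config$fs_eeg

  signal_unit <- convolve_kernel(envelope$values, truth$kernel)
  v_unit <- mean(apply(signal_unit, 2, var))
  signal <- config$coupling_gain * signal_unit

  seed0 <- child_seed(config$seed, 37)
  out <- with_seed(seed0, {
    noise <- pink_noise_matrix(n, fs, layout,
                               exponent = truth$noise_spectrum_exponent)
    target_var <- if (v_unit > 0) v_unit / 10^(config$snr_db / 10) else 25
    noise <- noise * sqrt(target_var / mean(apply(noise, 2, var)))
    if (orthogonalize && config$coupling_gain > 0) {
      for (j in seq_len(p)) {
        s <- signal[, j]
        ss <- sum(s * s)
        if (ss > 0) noise[, j] <- noise[, j] - sum(noise[, j] * s) / ss * s
      }
    }
    noise_sd <- sqrt(mean(apply(noise, 2, var)))

    artifact <- matrix(0, n, p)
    n_burst <- rpois(1, config$artifact_rate * config$duration / 60)
    bursts <- NULL
    if (n_burst > 0) {
      d_all <- gc_dist(layout$positions)
      for (b in seq_len(n_burst)) {
        dur <- runif(1, 0.3, 1)
        start <- runif(1, 0, max(config$duration - dur, 0))
        i0 <- max(1, round(start * fs)); i1 <- min(n, i0 + round(dur * fs))
        centre <- sample.int(p, 1)
        grp <- order(d_all[centre, ])[seq_len(sample(3:8, 1))]
        amp <- 30 * noise_sd
        artifact[i0:i1, grp] <- artifact[i0:i1, grp] +
          amp * matrix(rnorm((i1 - i0 + 1) * length(grp)), i1 - i0 + 1)
        bursts <- rbind(bursts, data.frame(
          start_s = (i0 - 1) / fs, end_s = (i1 - 1) / fs,
          channels = I(list(grp))))
      }
    }
    if (orthogonalize) {
      for (j in seq_len(p)) {
        a <- artifact[, j]
        if (any(a != 0)) {
          for (base in list(signal[, j], noise[, j])) {
            bb <- sum(base * base)
            if (bb > 0) a <- a - sum(a * base) / bb * base
          }
          artifact[, j] <- a
        }
      }
    }

    quality <- rep("good", p)
    bad_idx <- integer(0)
    if (config$bad_channel_count > 0) {
      bad_idx <- sample.int(p, min(config$bad_channel_count, p))
      quality[bad_idx] <- "bad"
    }
    list(noise = noise, artifact = artifact, quality = quality,
         bad_idx = bad_idx, bursts = bursts, noise_sd = noise_sd)
  })

  data <- signal + out$noise + out$artifact
  if (length(out$bad_idx) > 0) {
    bad_noise <- with_seed(child_seed(config$seed, 41),
      matrix(rnorm(n * length(out$bad_idx)), n) * 5 * out$noise_sd)
    data[, out$bad_idx] <- bad_noise
  }

  rec <- eeg_recording(data, fs, layout, reference = "vertex",
                       quality = out$quality)
  if (keep_parts) {
    attr(rec, "parts") <- list(signal = signal, noise = out$noise,
                               artifact = out$artifact)
    attr(rec, "artifacts") <- list(bursts = out$bursts,
                                   bad_channels = out$bad_idx)
  }
  truth$coupling_gain_used <- config$coupling_gain
  attr(rec, "ground_truth") <- truth[c("peak_latency_ms",
                                       "coupling_gain_used",
                                       "noise_spectrum_exponent")]
  rec
}
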