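#' Calibrate an artifact-subspace-reconstruction (ASR) model
#'
#' Estimates clean-EEG baseline statistics by self-calibration: the
#' recording is cut into non-overlapping windows, each window's RMS
#' amplitude (over all good channels) is ranked, and the cleanest
#' `clean_fraction` of windows forms the calibration set. The model
#' stores the calibration mean, covariance and its symmetric square root
#' (the mixing matrix used for reconstruction), together with the
#' detection threshold.
#'
#' @param recording an [eeg_recording()], at least `10 * window_len` long.
#' @param window_len sliding-window length in ms (default 500).
#' @param clean_fraction fraction of lowest-RMS windows used for
#'   calibration.
#' @param threshold_sd detection threshold in calibration standard
#'   deviations (default 20): a principal direction whose windowed
#'   variance exceeds `threshold_sd^2` times its calibration variance is
#'   reconstructed.
#' @return object of class `asr_model`.
#' @export
asr_calibrate <- function(recording, window_len = 500,
                          clean_fraction = 0.5, threshold_sd = 20) {
  stopifnot(inherits(recording, "eeg_recording"),
            clean_fraction > 0, clean_fraction <= 1, threshold_sd > 0)
  x <- recording$data
  w <- round(window_len / 1000 * recording$fs)
  n_win <- floor(nrow(x) / w)
  if (n_win < 10)
    stop("recording shorter than 10 windows; cannot calibrate",
         call. = FALSE)
  idx <- matrix(seq_len(n_win * w), nrow = w)
  rms <- apply(idx, 2, function(i) sqrt(mean(x[i, ]^2)))
  keep <- order(rms)[seq_len(max(1, floor(n_win * clean_fraction)))]
  calib <- x[as.vector(idx[, keep]), , drop = FALSE]
  mu <- colMeans(calib)
  cc <- sweep(calib, 2, mu)
  C <- crossprod(cc) / (nrow(cc) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  M <- e$vectors %*% (sqrt(ev) * t(e$vectors))   # symmetric sqrt of C
  structure(list(calibration_mean = mu, calibration_cov = C,
                 calibration_mixing = M, threshold_sd = threshold_sd,
                 window_len = window_len, fs = recording$fs,
                 channel_names = recording$layout$channel_names),
            class = "asr_model")
}

#' @export
print.asr_model <- function(x, ...) {
  cat(sprintf(
    "<asr_model> %d channels, window %g ms, threshold %g SD\n",
    length(x$calibration_mean), x$window_len, x$threshold_sd))
  invisible(x)
}

#' Clean a recording by artifact subspace reconstruction
#'
#' Slides a `window_len` window (50% overlap) over the recording. Each
#' window is decomposed by PCA; principal directions whose variance
#' exceeds `threshold_sd^2` times the calibration variance along that
#' direction are deemed corrupted and are reconstructed from the
#' remaining directions using the calibration mixing matrix
#' (`R = M (trunc(V'M))^+ V'`). Windows with no corrupted direction pass
#' through untouched. Overlapping windows are blended with a
#' raised-cosine overlap-add, so the output has exactly the input's
#' length and no boundary discontinuities.
#'
#' @param recording an [eeg_recording()].
#' @param model an [asr_calibrate()] model on the same channels.
#' @return cleaned `eeg_recording` (same dimensions, same reference).
#' @export
asr_clean <- function(recording, model) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(model, "asr_model"))
  if (!identical(model$channel_names, recording$layout$channel_names))
    stop("model channels do not match recording channels", call. = FALSE)
  x <- recording$data
  n <- nrow(x); p <- ncol(x)
  w <- round(model$window_len / 1000 * recording$fs)
  if (n < w) stop("recording shorter than one ASR window", call. = FALSE)
  hop <- max(1, w %/% 2)
  thr2 <- model$threshold_sd^2
  mu <- model$calibration_mean
  C <- model$calibration_cov
  M <- model$calibration_mixing

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1)) + 1e-6
  out <- matrix(0, n, p)
  acc <- numeric(n)
  starts <- unique(c(seq(1, max(1, n - w + 1), by = hop), n - w + 1))
  starts <- starts[starts >= 1]
  for (s0 in starts) {
    i <- s0:(s0 + w - 1)
    xi <- x[i, , drop = FALSE]
    xc <- sweep(xi, 2, mu)
    Cw <- crossprod(xc) / (w - 1)
    e <- eigen(Cw, symmetric = TRUE)
    calib_var <- colSums(e$vectors * (C %*% e$vectors))
    flagged <- e$values > thr2 * calib_var
    yi <- if (!any(flagged)) xi else {
      Vt <- t(e$vectors)
      A <- Vt %*% M
      A[flagged, ] <- 0
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      Ainv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      R <- M %*% Ainv %*% Vt
      sweep(xc %*% t(R), 2, mu, `+`)
    }
    out[i, ] <- out[i, ] + win * yi
    acc[i] <- acc[i] + win
  }
  out <- out / acc
  eeg_recording(out, recording$fs, recording$layout,
                reference = recording$reference, quality = recording$quality)
}

#' Interpolate bad channels from their neighbours
#'
#' Replaces each channel flagged `"bad"` by the inverse-distance-weighted
#' average of its `k_neighbors` nearest good channels (great-circle
#' distance on the unit sphere); weights are nonnegative and sum to one,
#' so a spatially constant field is reproduced exactly. Quality flags of
#' interpolated channels are reset to `"good"`.
#'
#' @param recording an [eeg_recording()].
#' @param k_neighbors neighbours per bad channel (default 6).
#' @return `eeg_recording` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(recording, k_neighbors = 6) {
  stopifnot(inherits(recording, "eeg_recording"))
  bad <- which(recording$quality == "bad")
  if (length(bad) == 0) return(recording)
  good <- which(recording$quality == "good")
  if (length(good) == 0)
    stop("all channels are bad; cannot interpolate", call. = FALSE)
  k <- min(k_neighbors, length(good))
  x <- recording$data
  pos <- recording$layout$positions
  for (b in bad) {
    d <- gc_dist(pos[b, ], pos[good, , drop = FALSE])
    nb <- good[order(d)[seq_len(k)]]
    dd <- pmax(d[order(d)[seq_len(k)]], 1e-9)
    wgt <- (1 / dd) / sum(1 / dd)
    x[, b] <- x[, nb, drop = FALSE] %*% wgt
  }
  q <- recording$quality
  q[bad] <- "good"
  eeg_recording(x, recording$fs, recording$layout,
                reference = recording$reference, quality = q)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over all electrodes from every
#' channel, so each sample's mean across channels becomes zero. The
#' operation is idempotent and updates the recording's reference state.
#'
#' @param recording an [eeg_recording()] with at least 2 channels.
#' @return average-referenced `eeg_recording`.
#' @export
rereference_average <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"),
            ncol(recording$data) >= 2)
  x <- recording$data - rowMeans(recording$data)
  eeg_recording(x, recording$fs, recording$layout,
                reference = "average", quality = recording$quality)
}

#' Downsample a recording
#'
#' Fourier-domain downsampling via [fft_resample()]: the spectrum is
#' truncated at the new Nyquist frequency (brick-wall anti-aliasing, so
#' content above `fs_new/2` is eliminated, far exceeding 40 dB
#' attenuation) and inverse-transformed at the new length
#' `floor(n * fs_new / fs)`.
#'
#' @param recording an [eeg_recording()].
#' @param fs_new target rate, Hz; must be strictly below the current rate.
#' @return resampled `eeg_recording`.
#' @export
resample_recording <- function(recording, fs_new) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (fs_new >= recording$fs)
    stop("fs_new must be below the current sampling rate", call. = FALSE)
  x <- fft_resample(recording$data, recording$fs, fs_new)
  eeg_recording(x, fs_new, recording$layout,
                reference = recording$reference, quality = recording$quality)
}

#' Remove periphery electrodes
#'
#' Drops exactly the channels whose layout periphery flag is set (face
#' and neck electrodes, conventionally removed before infant TRF
#' analysis), preserving the order of the surviving channels.
#'
#' @param recording an [eeg_recording()].
#' @return `eeg_recording` on the surviving channels.
#' @export
drop_periphery <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  keep <- which(!recording$layout$periphery)
  if (length(keep) == ncol(recording$data)) return(recording)
  eeg_recording(recording$data[, keep, drop = FALSE], recording$fs,
                layout_subset(recording$layout, keep),
                reference = recording$reference,
                quality = recording$quality[keep])
}

#' Cut fixed-length epochs and reject by amplitude
#'
#' Cuts consecutive non-overlapping epochs from the recording onset and
#' rejects any epoch in which any sample on any channel exceeds
#' `amp_threshold` in absolute value.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_len epoch length in seconds (default 1).
#' @param amp_threshold rejection threshold in microvolts (default 100).
#' @return object of class `epoch_set`: `epochs` (samples x channels x
#'   kept), `kept_idx`/`rejected_idx` (1-based epoch indices),
#'   `rejection_log` (index, peak uV), `epoch_len`, `fs`, `layout`.
#' @export
epoch_and_reject <- function(recording, epoch_len = 1,
                             amp_threshold = 100) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (epoch_len <= 0) stop("epoch_len must be positive", call. = FALSE)
  L <- round(epoch_len * recording$fs)
  n_ep <- floor(nrow(recording$data) / L)
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  peaks <- numeric(n_ep)
  for (ep in seq_len(n_ep)) {
    seg <- recording$data[((ep - 1) * L + 1):(ep * L), , drop = FALSE]
    peaks[ep] <- max(abs(seg))
  }
  kept <- which(peaks <= amp_threshold)
  rejected <- setdiff(seq_len(n_ep), kept)
  epochs <- array(0, c(L, ncol(recording$data), length(kept)))
  for (j in seq_along(kept)) {
    ep <- kept[j]
    epochs[, , j] <- recording$data[((ep - 1) * L + 1):(ep * L), ]
  }
  structure(list(epochs = epochs, kept_idx = kept, rejected_idx = rejected,
                 kept_count = length(kept), rejected_count = length(rejected),
                 rejection_log = data.frame(epoch = seq_len(n_ep),
                                            peak_uv = peaks,
                                            kept = peaks <= amp_threshold),
                 epoch_len = epoch_len, fs = recording$fs,
                 layout = recording$layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d kept / %d rejected epochs of %g s (%d channels)\n",
              x$kept_count, x$rejected_count, x$epoch_len, dim(x$epochs)[2]))
  invisible(x)
}

# Average-reference every epoch in place (mean over channels per sample).
epochs_rereference <- function(eset) {
  for (j in seq_len(dim(eset$epochs)[3]))
    eset$epochs[, , j] <- eset$epochs[, , j] -
      rowMeans(eset$epochs[, , j])
  eset
}
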