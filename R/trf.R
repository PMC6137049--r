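#' Extract the slow amplitude envelope of a signal
#'
#' Computes the magnitude of the analytic signal (FFT Hilbert
#' construction) of a broadband input, band-pass filters it with a
#' zero-phase 3rd-order Butterworth (applied forward-backward), and
#' resamples to `fs_out` by Fourier-domain resampling. When the input is
#' already an amplitude envelope (a `speech_envelope`), the analytic-
#' magnitude step is skipped and only filtering/resampling are applied.
#' Because the band-pass removes DC, the output can contain small
#' negative excursions; downstream regression is unaffected.
#'
#' @param x numeric audio vector, or a `speech_envelope`.
#' @param fs_in input sampling rate, Hz (taken from the object if `x` is
#'   a `speech_envelope`).
#' @param band band-pass edges in Hz, default `c(1, 8)`.
#' @param fs_out output rate, default 128 Hz.
#' @param register optional register label carried into the result.
#' @return a `speech_envelope` at `fs_out` with `band` set; length
#'   `floor(n * fs_out / fs_in)`.
#' @export
extract_envelope <- function(x, fs_in = NULL, band = c(1, 8),
                             fs_out = 128, register = NULL) {
  is_env <- inherits(x, "speech_envelope")
  if (is_env) {
    fs_in <- x$fs
    register <- register %||% x$register
    x <- x$values
  }
  stopifnot(is.numeric(x), !is.null(fs_in), length(band) == 2)
  if (length(x) < 3 * fs_in / band[1])
    stop("input shorter than 3 filter lengths of the low band edge",
         call. = FALSE)
  env <- if (is_env) x else Mod(analytic_signal(x))
  env <- bandpass_filtfilt(env, fs_in, band, order = 3)
  if (fs_out != fs_in) env <- fft_resample(env, fs_in, fs_out)
  structure(list(values = env, fs = fs_out, register = register,
                 band = band),
            class = "speech_envelope")
}

#' Lag grid for a TRF window
#'
#' @param fs sampling rate, Hz.
#' @param tmin,tmax window edges in ms (default 0-500).
#' @return vector of lags in ms at the sampling step.
#' @export
trf_lags <- function(fs, tmin = 0, tmax = 500) {
  seq(tmin, tmax, by = 1000 / fs)
}

#' Build the time-lagged design matrix
#'
#' Column j holds the envelope delayed by lag_j (`X[t, j] =
#' envelope[t - lag_j]`), with out-of-range samples zero-padded, plus a
#' trailing constant column for the intercept.
#'
#' @param envelope numeric vector or `speech_envelope`.
#' @param fs sampling rate (taken from the object when omitted).
#' @param lags_ms lag grid in ms (see [trf_lags()]).
#' @return numeric matrix, time x (lags + 1); the lag columns are named
#'   by their ms value, the last column is `"(Intercept)"`.
#' @export
build_lagged_design <- function(envelope, fs = NULL,
                                lags_ms = trf_lags(fs)) {
  if (inherits(envelope, "speech_envelope")) {
    fs <- fs %||% envelope$fs
    envelope <- envelope$values
  }
  stopifnot(!is.null(fs))
  n <- length(envelope)
  shifts <- round(lags_ms * fs / 1000)
  if (any(shifts >= n))
    stop("lags exceed the signal length", call. = FALSE)
  if (any(shifts < 0))
    stop("negative lags are outside the supported 0-500 ms window",
         call. = FALSE)
  X <- matrix(0, n, length(shifts) + 1)
  for (j in seq_along(shifts)) {
    s <- shifts[j]
    X[(s + 1):n, j] <- envelope[seq_len(n - s)]
  }
  X[, length(shifts) + 1] <- 1
  colnames(X) <- c(sprintf("%.4g", lags_ms), "(Intercept)")
  X
}

# Ridge solve shared by fit_trf and crossval_predict: lag columns are
# penalized by lambda times the mean diagonal of X'X (so lambda = 1 is
# scale-free); the intercept is unpenalized.
ridge_solve <- function(X, Y, lambda) {
  k <- ncol(X) - 1
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  m <- mean(diag(XtX)[seq_len(k)])
  pen <- diag(c(rep(lambda * m, k), 0), ncol(X))
  solve(XtX + pen, XtY)
}

#' Fit a forward temporal response function by ridge regression
#'
#' Regresses the EEG at every channel onto the time-lagged speech
#' envelope: `w = (X'X + lambda * m * I)^-1 X'y`, where X is the lagged
#' design (intercept unpenalized) and the penalty is normalized by `m`,
#' the mean diagonal of `X'X` over lag columns, so `lambda = 1` is
#' comparable across inputs of different scale. The resulting per-channel
#' weight vectors over the 0-500 ms lag window are the TRFs.
#'
#' @param envelope `speech_envelope` (or numeric vector) aligned with and
#'   sampled at the recording's rate.
#' @param recording an [eeg_recording()] at the same rate.
#' @param lambda ridge parameter, default 1.
#' @param lags_ms lag grid in ms, default 0-500 at the sampling step.
#' @return object of class `trf_model`: `weights` (lags x channels, uV
#'   per unit envelope), `intercept`, `lag_ms`, `lambda`, `fs`,
#'   `channel_names`.
#' @export
fit_trf <- function(envelope, recording, lambda = 1,
                    lags_ms = NULL) {
  if (inherits(envelope, "speech_envelope")) {
    if (abs(envelope$fs - recording$fs) > 1e-9)
      stop("envelope and recording rates differ", call. = FALSE)
    env <- envelope$values
  } else env <- envelope
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(env) != nrow(recording$data))
    stop("envelope and EEG lengths differ", call. = FALSE)
  if (sd(env) == 0)
    stop("degenerate input: envelope has zero variance", call. = FALSE)
  lags_ms <- lags_ms %||% trf_lags(recording$fs)
  X <- build_lagged_design(env, recording$fs, lags_ms)
  W <- ridge_solve(X, recording$data, lambda)
  k <- length(lags_ms)
  structure(list(weights = W[seq_len(k), , drop = FALSE],
                 intercept = W[k + 1, ], lag_ms = lags_ms,
                 lambda = lambda, fs = recording$fs,
                 channel_names = recording$layout$channel_names),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf(
    "<trf_model> %d lags (%g-%g ms) x %d channels, lambda = %g\n",
    length(x$lag_ms), min(x$lag_ms), max(x$lag_ms),
    ncol(x$weights), x$lambda))
  invisible(x)
}

#' Cross-validated EEG prediction from the speech envelope
#'
#' Splits the recording into `n_folds` contiguous time folds; for each
#' fold, a TRF is fitted on the remaining folds and used to predict the
#' held-out EEG, scored by the per-channel Pearson correlation between
#' prediction and recording. Envelope and EEG are z-scored with training-
#' fold statistics before fitting; lagged designs are built per contiguous
#' segment so no training sample leaks across a fold boundary.
#'
#' @inheritParams fit_trf
#' @param n_folds number of contiguous folds, default 5; every fold must
#'   span at least 10 s.
#' @return object of class `prediction_scores`: `r` (folds x channels),
#'   `mean_r` (per channel), `n_folds`, `folds` (sample ranges),
#'   `channel_names`.
#' @export
crossval_predict <- function(envelope, recording, lambda = 1,
                             n_folds = 5, lags_ms = NULL) {
  if (inherits(envelope, "speech_envelope")) {
    if (abs(envelope$fs - recording$fs) > 1e-9)
      stop("envelope and recording rates differ", call. = FALSE)
    env <- envelope$values
  } else env <- envelope
  stopifnot(inherits(recording, "eeg_recording"))
  n <- nrow(recording$data)
  if (length(env) != n)
    stop("envelope and EEG lengths differ", call. = FALSE)
  lags_ms <- lags_ms %||% trf_lags(recording$fs)
  bounds <- floor(n * (0:n_folds) / n_folds)
  if (min(diff(bounds)) < 10 * recording$fs)
    stop("recording too short: every fold must span at least 10 s",
         call. = FALSE)
  p <- ncol(recording$data)
  r <- matrix(NA_real_, n_folds, p)
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- (bounds[f] + 1):bounds[f + 1]
    folds[[f]] <- range(test)
    train_segs <- list(seq_len(bounds[f]),
                       if (bounds[f + 1] < n) (bounds[f + 1] + 1):n
                       else integer(0))
    train_segs <- Filter(length, train_segs)
    tr_idx <- unlist(train_segs)
    mu_e <- mean(env[tr_idx]); sd_e <- max(sd(env[tr_idx]), 1e-12)
    mu_y <- colMeans(recording$data[tr_idx, , drop = FALSE])
    sd_y <- pmax(apply(recording$data[tr_idx, , drop = FALSE], 2, sd),
                 1e-12)
    zX <- do.call(rbind, lapply(train_segs, function(i)
      build_lagged_design((env[i] - mu_e) / sd_e, recording$fs, lags_ms)))
    zY <- sweep(sweep(recording$data[tr_idx, , drop = FALSE], 2, mu_y),
                2, sd_y, `/`)
    W <- ridge_solve(zX, zY, lambda)
    Xt <- build_lagged_design((env[test] - mu_e) / sd_e, recording$fs,
                              lags_ms)
    pred <- Xt %*% W
    yt <- sweep(sweep(recording$data[test, , drop = FALSE], 2, mu_y),
                2, sd_y, `/`)
    for (ch in seq_len(p)) {
      if (sd(pred[, ch]) > 0 && sd(yt[, ch]) > 0)
        r[f, ch] <- cor(pred[, ch], yt[, ch])
      else r[f, ch] <- 0
    }
  }
  colnames(r) <- recording$layout$channel_names
  structure(list(r = r, mean_r = colMeans(r), n_folds = n_folds,
                 folds = folds,
                 channel_names = recording$layout$channel_names),
            class = "prediction_scores")
}

#' @export
print.prediction_scores <- function(x, ...) {
  cat(sprintf(
    "<prediction_scores> %d folds x %d channels, grand mean r = %.4f\n",
    x$n_folds, length(x$mean_r), mean(x$mean_r)))
  invisible(x)
}

#' Grand-average TRF across subjects
#'
#' Element-wise mean of the weights (and intercepts) of per-subject TRF
#' models sharing one lag grid and channel set.
#'
#' @param models list of `trf_model` objects.
#' @return a `trf_model` with averaged weights; `attr(, "n_averaged")`
#'   records the number of models.
#' @export
grand_average_trf <- function(models) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, TRUE, "trf_model")))
  ref <- models[[1]]
  for (m in models[-1]) {
    if (!isTRUE(all.equal(m$lag_ms, ref$lag_ms)) ||
        !identical(m$channel_names, ref$channel_names))
      stop("models have mismatched lag grids or channel sets",
           call. = FALSE)
  }
  W <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  b <- Reduce(`+`, lapply(models, `[[`, "intercept")) / length(models)
  out <- ref
  out$weights <- W
  out$intercept <- b
  attr(out, "n_averaged") <- length(models)
  out
}

#' @export
plot.trf_model <- function(x, channels = NULL, ...) {
  sel <- channels %||% seq_len(ncol(x$weights))
  graphics::matplot(x$lag_ms, x$weights[, sel, drop = FALSE], type = "l",
                    lty = 1, xlab = "lag (ms)",
                    ylab = expression(paste("TRF weight (", mu, "V)")),
                    ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}
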