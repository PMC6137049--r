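#' Generate a ground-truth stimulus-response kernel
#'
#' Builds the simulated cortical impulse response (the ground-truth TRF)
#' that couples the speech envelope to each EEG channel. The temporal
#' shape is biphasic -- a positive raised-cosine component centred on
#' `peak_latency` followed by a negative trough ~120 ms later -- and is
#' identically zero at the edges of the 0-500 ms lag window. The two
#' phases have balanced areas, so the kernel integrates to roughly zero
#' and the nonnegative envelope produces no standing DC offset in the
#' response.
#' Spatially the kernel is weighted toward left-frontal channels via a
#' smooth gain field centred over the left-frontal scalp, mimicking the
#' left-lateralized frontal auditory response the analysis is designed to
#' detect. A small seeded per-channel gain jitter breaks exact symmetry.
#'
#' @param layout an [make_layout()] layout.
#' @param peak_latency positive-peak latency in ms, strictly inside
#'   (0, 500).
#' @param seed integer seed for the per-channel gain jitter.
#' @param fs sampling rate (Hz) of the lag grid.
#' @param lag_max last lag of the window, ms.
#' @param peak_uv kernel amplitude at the peak, microvolts per unit
#'   envelope.
#' @return an object of class `trf_ground_truth`: list with `kernel`
#'   (lags x channels, uV per unit envelope), `lag_ms`, `fs`,
#'   `peak_latency_ms`, `noise_spectrum_exponent`, `coupling_gain_used`
#'   (NA until [simulate_eeg()] uses it).
#' @export
generate_kernel <- function(layout, peak_latency = 85, seed = 1,
                            fs = 128, lag_max = 500, peak_uv = 2) {
  stopifnot(inherits(layout, "eeg_layout"))
  if (peak_latency <= 0 || peak_latency >= 500)
    stop("peak_latency must lie strictly inside (0, 500) ms", call. = FALSE)
  lag_ms <- seq(0, lag_max, by = 1000 / fs)
  bump <- function(t, centre, width) {
    out <- numeric(length(t))
    in_ <- abs(t - centre) < width
    out[in_] <- cos(pi * (t[in_] - centre) / (2 * width))^2
    out
  }
  # trough amplitude 0.75 = 60/80 balances the two phases' areas, so the
  # kernel integrates to ~0 and the response carries no DC offset
  shape <- bump(lag_ms, peak_latency, 60) -
    0.75 * bump(lag_ms, peak_latency + 120, 80)
  shape[c(1, length(shape))] <- 0               # hard zero at window edges

  centre_fl <- c(-0.45, 0.72, 0.52)
  centre_fl <- centre_fl / sqrt(sum(centre_fl^2))
  d <- gc_dist(centre_fl, layout$positions)
  gain <- 0.15 + 0.85 * exp(-(d / 0.8)^2)
  gain <- gain * with_seed(child_seed(seed, 23),
                           runif(length(gain), 0.92, 1.08))
  kernel <- outer(shape, gain)
  kernel <- kernel * (peak_uv / max(abs(kernel)))
  colnames(kernel) <- layout$channel_names

  structure(list(kernel = kernel, lag_ms = lag_ms, fs = fs,
                 peak_latency_ms = peak_latency,
                 noise_spectrum_exponent = 2,
                 coupling_gain_used = NA_real_,
                 layout = layout),
            class = "trf_ground_truth")
}

#' @export
print.trf_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<trf_ground_truth> %d lags (0-%g ms at %g Hz) x %d channels, peak %g ms\n",
    length(x$lag_ms), max(x$lag_ms), x$fs, ncol(x$kernel),
    x$peak_latency_ms))
  invisible(x)
}
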