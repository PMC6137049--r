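#' Generate a synthetic speech amplitude envelope
#'
#' Produces a nonnegative envelope emulating the slow amplitude
#' modulations of continuous natural speech: Gamma-shaped syllable pulses
#' arriving as a Poisson process, multiplied by a slow utterance-level
#' modulator. The two registers differ as infant- vs adult-directed
#' speech do acoustically: the IDS setting uses a slower syllable rate
#' (2.9/s vs 3.8/s, mirroring the registers' word rates) and a deeper,
#' slower utterance modulation, so at matched total variance IDS carries
#' more modulation power below 2 Hz and a lower overall modulation rate.
#' The envelope is standardized to unit variance, keeping the register
#' contrast a matter of spectral shape, not level.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `speech_envelope`: list with `values`
#'   (nonnegative, length `round(duration * fs_envelope)`), `fs`,
#'   `register`, `band` (NULL until filtered).
#' @export
generate_envelope <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs_envelope
  n <- round(config$duration * fs)
  ids <- config$register == "IDS"
  rate <- if (ids) 2.9 else 3.8         # syllable pulses per second
  pulse_scale <- if (ids) 0.060 else 0.045  # Gamma scale, seconds
  depth <- if (ids) 0.9 else 0.35       # utterance-modulator depth
  mod_cutoff <- if (ids) 0.5 else 0.8   # Hz

  vals <- with_seed(child_seed(config$seed, 11), {
    n_ev <- rpois(1, rate * config$duration)
    spikes <- numeric(n)
    if (n_ev > 0) {
      at <- pmax(1, ceiling(runif(n_ev) * n))
      amp <- rlnorm(n_ev, 0, 0.3)
      for (i in seq_len(n_ev)) spikes[at[i]] <- spikes[at[i]] + amp[i]
    }
    tk <- seq(0, 0.6, by = 1 / fs)
    kern <- stats::dgamma(tk, shape = 2, scale = pulse_scale)
    pulses <- stats::convolve(spikes, rev(kern), type = "open")[seq_len(n)]
    pulses <- pmax(pulses, 0)      # FFT convolution round-off
    slow <- rnorm(n)
    slow <- lowpass_filtfilt(slow, fs, mod_cutoff, order = 2)
    slow <- slow / max(sd(slow), 1e-12)
    modulator <- pmax(0.05, 1 + depth * slow)
    pulses * modulator
  })
  s <- sd(vals)
  if (s > 0) vals <- vals / s           # matched total variance across runs
  structure(list(values = vals, fs = fs, register = config$register,
                 band = NULL),
            class = "speech_envelope")
}

#' @export
print.speech_envelope <- function(x, ...) {
  cat(sprintf("<speech_envelope> %s: %d samples at %g Hz (%.1f s)%s\n",
              x$register %||% "?", length(x$values), x$fs,
              length(x$values) / x$fs,
              if (is.null(x$band)) ""
              else sprintf(", band %g-%g Hz", x$band[1], x$band[2])))
  invisible(x)
}

# One-sided DFT modulation power of a (mean-removed) envelope; used by the
# register-contrast checks and by extract_envelope tests.
modulation_power <- function(values, fs, band) {
  n <- length(values)
  x <- values - mean(values)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= band[1] & f <= band[2]]) * 2
}
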