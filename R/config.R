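#' Simulation configuration for one synthetic subject/register run
#'
#' Bundles and validates the parameters of the synthetic two-register
#' listening study. Defaults emulate the study conditions the generator is
#' built around: ~8-minute continuous recordings, an infant-directed (IDS)
#' vs adult-directed (ADS) register contrast carried by the envelope's
#' slow modulation and by the stimulus-EEG coupling strength, pink
#' (1/f^2) background EEG, occasional movement-artifact bursts, and a
#' small number of dead/bridged channels.
#'
#' `coupling_gain` scales the envelope-convolved cortical response;
#' `snr_db` fixes the noise floor relative to the *unit-coupling* response
#' variance, so lowering `coupling_gain` lowers the effective SNR rather
#' than the noise.
#'
#' @param n_subjects number of simulated subjects (used by the pipeline).
#' @param duration recording length in seconds.
#' @param fs_eeg EEG sampling rate, Hz.
#' @param fs_envelope envelope sampling rate, Hz (defaults to `fs_eeg`).
#' @param register `"IDS"` or `"ADS"`.
#' @param coupling_gain unitless stimulus-EEG coupling (>= 0).
#' @param snr_db signal-to-noise ratio in dB at unit coupling.
#' @param artifact_rate artifact bursts per minute.
#' @param bad_channel_count channels replaced by high-variance noise.
#' @param seed integer seed; all generator draws derive from it.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_subjects = 12, duration = 480, fs_eeg = 250,
                       fs_envelope = fs_eeg,
                       register = c("IDS", "ADS"),
                       coupling_gain = NULL, snr_db = 0,
                       artifact_rate = 2, bad_channel_count = 2,
                       seed = 1) {
  register <- match.arg(register)
  if (is.null(coupling_gain))
    coupling_gain <- if (register == "IDS") 1 else 0
  stopifnot(duration > 0, fs_eeg > 20, fs_envelope > 20,
            coupling_gain >= 0, artifact_rate >= 0,
            bad_channel_count >= 0, n_subjects >= 1)
  structure(list(
    n_subjects = as.integer(n_subjects), duration = duration,
    fs_eeg = fs_eeg, fs_envelope = fs_envelope, register = register,
    coupling_gain = coupling_gain, snr_db = snr_db,
    artifact_rate = artifact_rate,
    bad_channel_count = as.integer(bad_channel_count),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s register: %d subjects, %gs at %g Hz, coupling %g, snr %g dB\n",
    x$register, x$n_subjects, x$duration, x$fs_eeg, x$coupling_gain,
    x$snr_db))
  invisible(x)
}
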