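# Small fixtures shared across test files; everything is generated in
# code under fixed seeds.

tiny_layout <- function(n = 16, seed = 1) make_layout(n, seed = seed)

quick_cfg <- function(duration = 30, fs = 128, register = "IDS",
                      coupling_gain = 1, snr_db = 0, artifact_rate = 0,
                      bad_channel_count = 0, seed = 1) {
  sim_config(n_subjects = 1, duration = duration, fs_eeg = fs,
             register = register, coupling_gain = coupling_gain,
             snr_db = snr_db, artifact_rate = artifact_rate,
             bad_channel_count = bad_channel_count, seed = seed)
}

# envelope + kernel + recording triple at small scale
sim_small <- function(duration = 30, fs = 128, n_channels = 16,
                      seed = 1, peak_latency = 85, ...) {
  lay <- make_layout(n_channels, seed = 1)
  cfg <- quick_cfg(duration = duration, fs = fs, seed = seed, ...)
  env <- generate_envelope(cfg)
  truth <- generate_kernel(lay, peak_latency, seed = 2, fs = fs)
  rec <- simulate_eeg(env, truth, cfg, keep_parts = TRUE)
  list(layout = lay, cfg = cfg, env = env, truth = truth, rec = rec)
}

# t-map cluster helpers
has_significant <- function(res)
  any(vapply(res$clusters, function(cl) isTRUE(cl$significant), TRUE))

significant_clusters <- function(res)
  Filter(function(cl) isTRUE(cl$significant), res$clusters)
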