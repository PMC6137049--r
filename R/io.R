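#' Write / read an EEG recording as CSV plus JSON metadata
#'
#' The sample matrix goes to `<path>` (one column per channel, header
#' row of channel names); sampling rate, reference state, quality flags
#' and the layout go to `<path>.meta.json`. The pair round-trips a
#' recording losslessly up to numeric printing precision.
#'
#' @param recording an [eeg_recording()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  data.table::fwrite(as.data.frame(recording$data), path)
  meta <- list(fs = recording$fs, reference = recording$reference,
               quality = recording$quality,
               layout = unclass(recording$layout))
  meta$layout$positions <- unname(apply(recording$layout$positions, 1,
                                        function(r) r, simplify = FALSE))
  meta$layout$region <- as.character(recording$layout$region)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  x <- as.matrix(data.table::fread(path))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  layout <- structure(list(
    channel_names = meta$layout$channel_names,
    positions = do.call(rbind, lapply(meta$layout$positions, unlist)),
    region = factor(meta$layout$region,
                    levels = c("frontal-left", "frontal-right", "other")),
    periphery = meta$layout$periphery,
    reference_channel = meta$layout$reference_channel
  ), class = "eeg_layout")
  eeg_recording(x, meta$fs, layout, reference = meta$reference,
                quality = meta$quality)
}

#' Write / read a speech envelope as CSV
#'
#' Two columns: `time_s` and `value`; rate, register and band are stored
#' in a JSON sidecar.
#'
#' @param envelope a `speech_envelope`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_envelope_csv <- function(envelope, path) {
  stopifnot(inherits(envelope, "speech_envelope"))
  n <- length(envelope$values)
  data.table::fwrite(data.frame(time_s = (seq_len(n) - 1) / envelope$fs,
                                value = envelope$values), path)
  jsonlite::write_json(list(fs = envelope$fs,
                            register = envelope$register,
                            band = envelope$band),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envelope_csv
#' @export
read_envelope_csv <- function(path) {
  x <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(values = x$value, fs = meta$fs,
                 register = meta$register,
                 band = if (length(meta$band)) meta$band else NULL),
            class = "speech_envelope")
}

#' Serialize a ground-truth kernel to JSON
#'
#' @param truth a [generate_kernel()] ground truth.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "trf_ground_truth"))
  out <- list(lag_ms = truth$lag_ms, fs = truth$fs,
              peak_latency_ms = truth$peak_latency_ms,
              noise_spectrum_exponent = truth$noise_spectrum_exponent,
              coupling_gain_used = truth$coupling_gain_used,
              channel_names = colnames(truth$kernel),
              kernel = unname(apply(truth$kernel, 2, function(cc) cc,
                                    simplify = FALSE)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize cluster-test results to JSON
#'
#' One record per cluster: member (channel, time) pairs, mass t-score,
#' permutation p-value, sign and significance flag.
#'
#' @param result a [permutation_test()] `cluster_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  recs <- lapply(result$clusters, function(cl) list(
    channels = cl$channels,
    electrode = unname(cl$members[, "electrode"]),
    time = unname(cl$members[, "time"]),
    time_values = cl$time_values,
    mass_t = cl$mass_t, p = cl$p, sign = cl$sign,
    significant = cl$significant))
  jsonlite::write_json(list(n_permutations = result$n_permutations,
                            alpha = result$alpha, clusters = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a TRF model's weights as CSV (channel x lag)
#'
#' @param model a [fit_trf()] `trf_model`.
#' @param path output CSV path; metadata goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trf_csv <- function(model, path) {
  stopifnot(inherits(model, "trf_model"))
  w <- t(model$weights)
  colnames(w) <- sprintf("lag_%.4gms", model$lag_ms)
  out <- data.frame(channel = model$channel_names, w,
                    check.names = FALSE)
  data.table::fwrite(out, path)
  jsonlite::write_json(list(lambda = model$lambda, fs = model$fs,
                            lag_ms = model$lag_ms,
                            intercept = model$intercept),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
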