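#' Configuration for an end-to-end synthetic study run
#'
#' Collects every stage parameter of the simulate -> preprocess -> power
#' -> TRF -> cluster-statistics pipeline, with defaults mirroring the
#' two-register infant listening design the package emulates: 12
#' subjects, one shared IDS and one shared ADS stimulus envelope, a
#' left-frontal ground-truth kernel peaking at 85 ms, ASR with a 500 ms
#' window at 20 SD, 1-s epochs rejected at +/-100 uV, theta band 4-8 Hz,
#' ridge TRFs over 0-500 ms lags at lambda = 1 with 5-fold
#' cross-validated prediction, and 1000-permutation cluster tests.
#' Unknown arguments are rejected. All parameters are echoed verbatim
#' into the run report.
#'
#' @param n_subjects simulated subjects.
#' @param duration recording length per register, seconds.
#' @param n_channels electrodes in the layout.
#' @param fs_eeg simulation sampling rate, Hz.
#' @param coupling_gain named vector `c(IDS = , ADS = )` of register
#'   coupling gains.
#' @param coupling_jitter_sd between-subject log-normal coupling
#'   variability (log scale SD).
#' @param snr_db noise floor relative to the unit-coupling response.
#' @param artifact_rate bursts per minute.
#' @param bad_channel_count bad channels per subject; scalar or one
#'   value per subject.
#' @param peak_latency ground-truth kernel peak, ms.
#' @param asr_window,asr_threshold,asr_clean_fraction ASR parameters
#'   (ms, SD, fraction).
#' @param k_neighbors neighbours for bad-channel interpolation.
#' @param fs_power sampling rate of the power branch, Hz.
#' @param epoch_len,amp_threshold epoching parameters (s, uV).
#' @param theta_band analysis band for regional power, Hz.
#' @param fs_trf sampling rate of the TRF branch, Hz.
#' @param env_band envelope band-pass, Hz.
#' @param lambda ridge parameter.
#' @param lag_window TRF lag window, ms.
#' @param n_folds cross-validation folds.
#' @param n_permutations,cluster_alpha,alpha cluster-test parameters.
#' @param adjacency_max_dist adjacency radius (radians) or `NULL` for
#'   the geometric default.
#' @param max_bad_channels subjects with more simulated bad channels are
#'   excluded (with a logged reason).
#' @param word_counts,durations_s named IDS/ADS stimulus descriptives
#'   used for the summary speech rates.
#' @param formants optional named list of 3 x 2 (F1, F2) corner-vowel
#'   matrices per register for vowel-space areas.
#' @param seed master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @param out_dir optional directory for stage artifacts (CSV/JSON).
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 12, duration = 300, n_channels = 64,
                       fs_eeg = 250,
                       coupling_gain = c(IDS = 1, ADS = 0),
                       coupling_jitter_sd = 0.15,
                       snr_db = 0, artifact_rate = 2,
                       bad_channel_count = 2, peak_latency = 85,
                       asr_window = 500, asr_threshold = 20,
                       asr_clean_fraction = 0.5, k_neighbors = 6,
                       fs_power = 250, epoch_len = 1,
                       amp_threshold = 100, theta_band = c(4, 8),
                       fs_trf = 128, env_band = c(1, 8), lambda = 1,
                       lag_window = c(0, 500), n_folds = 5,
                       n_permutations = 1000, cluster_alpha = 0.05,
                       alpha = 0.05, adjacency_max_dist = NULL,
                       max_bad_channels = 20,
                       word_counts = c(IDS = 1384, ADS = 1810),
                       durations_s = c(IDS = 486, ADS = 481),
                       formants = NULL, seed = 1, out_dir = NULL) {
  stopifnot(all(c("IDS", "ADS") %in% names(coupling_gain)),
            n_subjects >= 1, duration > 0, fs_trf <= fs_eeg,
            fs_power <= fs_eeg, length(lag_window) == 2)
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %d subjects, %gs at %g Hz, %d channels, seed %d\n",
    x$n_subjects, x$duration, x$fs_eeg, x$n_channels, x$seed))
  invisible(x)
}

#' Run the full synthetic two-register analysis pipeline
#'
#' Executes, for every subject and both registers: simulation (shared
#' per-register stimulus envelope, shared ground-truth kernel,
#' subject-specific noise/artifacts and coupling jitter), ASR cleaning
#' and bad-channel interpolation, then the two analysis branches -- (a)
#' downsample, epoch, amplitude-reject, average-reference, Hanning
#' spectrum, theta-band frontal power; (b) average-reference, periphery
#' removal, downsample, ridge TRF and cross-validated prediction --
#' followed by the group statistics: register x hemisphere
#' repeated-measures ANOVA on theta power, a paired cluster-mass
#' permutation test on the IDS-ADS TRF difference over (electrode, lag)
#' points, and one-sample spatial cluster tests of the prediction
#' correlations per register. Subjects exceeding `max_bad_channels`
#' simulated bad channels are excluded with a logged reason, never
#' silently dropped.
#'
#' @param config a [run_config()].
#' @return object of class `run_report`; regenerable bit-identically
#'   from the same config (the config, including its seed, is echoed in
#'   the report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  layout <- make_layout(config$n_channels, seed = child_seed(seed, 1))
  truth <- generate_kernel(layout, config$peak_latency,
                           seed = child_seed(seed, 2),
                           fs = config$fs_eeg,
                           lag_max = config$lag_window[2])
  say("layout: %d channels (%d periphery); kernel peak %g ms",
      config$n_channels, sum(layout$periphery), config$peak_latency)

  registers <- c("IDS", "ADS")
  env_raw <- lapply(seq_along(registers), function(i) {
    generate_envelope(sim_config(
      n_subjects = 1, duration = config$duration,
      fs_eeg = config$fs_eeg, register = registers[i],
      coupling_gain = config$coupling_gain[[registers[i]]],
      snr_db = config$snr_db, seed = child_seed(seed, 4 + i)))
  })
  names(env_raw) <- registers
  env_trf <- lapply(env_raw, extract_envelope, band = config$env_band,
                    fs_out = config$fs_trf)

  jitter <- with_seed(child_seed(seed, 3),
                      rlnorm(config$n_subjects, 0, config$coupling_jitter_sd))
  bad_counts <- rep(config$bad_channel_count,
                    length.out = config$n_subjects)
  lags_ms <- trf_lags(config$fs_trf, config$lag_window[1],
                      config$lag_window[2])

  power_rows <- list()
  trf_models <- list(IDS = list(), ADS = list())
  cv_scores <- list(IDS = list(), ADS = list())
  epoch_log <- list()
  exclusions <- data.frame(subject = integer(0), reason = character(0))
  analyzed <- integer(0)
  layout_trf <- NULL

  for (s in seq_len(config$n_subjects)) {
    sub_recs <- list()
    excluded <- FALSE
    for (reg in registers) {
      cfg <- sim_config(
        n_subjects = 1, duration = config$duration,
        fs_eeg = config$fs_eeg, register = reg,
        coupling_gain = config$coupling_gain[[reg]] * jitter[s],
        snr_db = config$snr_db, artifact_rate = config$artifact_rate,
        bad_channel_count = bad_counts[s],
        seed = child_seed(seed, 100 + 10 * s + (reg == "ADS")))
      rec <- simulate_eeg(env_raw[[reg]], truth, cfg)
      n_bad <- sum(rec$quality == "bad")
      if (n_bad > config$max_bad_channels) {
        exclusions <- rbind(exclusions, data.frame(
          subject = s,
          reason = sprintf("%d bad channels (> %d)", n_bad,
                           config$max_bad_channels)))
        say("subject %d EXCLUDED: %d bad channels", s, n_bad)
        excluded <- TRUE
        break
      }
      sub_recs[[reg]] <- rec
    }
    if (excluded) next
    analyzed <- c(analyzed, s)

    for (reg in registers) {
      rec <- sub_recs[[reg]]
      model <- asr_calibrate(rec, config$asr_window,
                             config$asr_clean_fraction,
                             config$asr_threshold)
      rec <- asr_clean(rec, model)
      rec <- interpolate_bad_channels(rec, config$k_neighbors)

      # branch A: theta power
      rec_a <- if (config$fs_power < config$fs_eeg)
        resample_recording(rec, config$fs_power) else rec
      es <- epoch_and_reject(rec_a, config$epoch_len,
                             config$amp_threshold)
      es <- epochs_rereference(es)
      psd <- power_spectrum(es)
      brp <- band_region_power(psd, config$theta_band)
      power_rows[[length(power_rows) + 1]] <- data.frame(
        subject = s, register = reg, region = brp$region,
        theta_power = brp$power)
      epoch_log[[length(epoch_log) + 1]] <- data.frame(
        subject = s, register = reg, kept = es$kept_count,
        rejected = es$rejected_count)
      say("subject %d %s: %d/%d epochs kept", s, reg, es$kept_count,
          es$kept_count + es$rejected_count)

      # branch B: TRF + prediction
      rec_b <- rereference_average(rec)
      rec_b <- drop_periphery(rec_b)
      rec_b <- resample_recording(rec_b, config$fs_trf)
      layout_trf <- rec_b$layout
      trf_models[[reg]][[as.character(s)]] <-
        fit_trf(env_trf[[reg]], rec_b, config$lambda, lags_ms)
      cv_scores[[reg]][[as.character(s)]] <-
        crossval_predict(env_trf[[reg]], rec_b, config$lambda,
                         config$n_folds, lags_ms)
    }
  }

  n_analyzed <- length(analyzed)
  say("analyzed %d subjects, excluded %d", n_analyzed, nrow(exclusions))
  power_table <- do.call(rbind, power_rows)
  anova <- NULL
  if (n_analyzed >= 3) anova <- rm_anova_2x2(power_table)

  trf_grand <- lapply(trf_models, function(ms)
    if (length(ms)) grand_average_trf(unname(ms)) else NULL)
  trf_cluster <- NULL
  prediction_clusters <- list(IDS = NULL, ADS = NULL)
  adjacency <- NULL
  if (n_analyzed >= 3) {
    adjacency <- build_adjacency(layout_trf, config$adjacency_max_dist)
    arr <- lapply(registers, function(reg) {
      ws <- lapply(trf_models[[reg]], function(m) t(m$weights))
      array(unlist(ws), c(dim(ws[[1]]), length(ws)))
    })
    # reorder to subjects x electrodes x lags
    arr <- lapply(arr, function(a) aperm(a, c(3, 1, 2)))
    trf_cluster <- permutation_test(
      arr[[1]], arr[[2]], adjacency,
      n_permutations = config$n_permutations,
      seed = child_seed(seed, 71),
      cluster_alpha = config$cluster_alpha, alpha = config$alpha,
      times = lags_ms)
    for (i in seq_along(registers)) {
      rmat <- do.call(rbind,
                      lapply(cv_scores[[registers[i]]], `[[`, "mean_r"))
      prediction_clusters[[registers[i]]] <- prediction_cluster_test(
        rmat, adjacency, n_permutations = config$n_permutations,
        seed = child_seed(seed, 72 + i),
        cluster_alpha = config$cluster_alpha, alpha = config$alpha)
    }
  }

  stimulus <- list(
    speech_rate = c(IDS = speech_rate(config$word_counts[["IDS"]],
                                      config$durations_s[["IDS"]]),
                    ADS = speech_rate(config$word_counts[["ADS"]],
                                      config$durations_s[["ADS"]])),
    vowel_area = if (!is.null(config$formants))
      vapply(config$formants, vowel_triangle_area, 0) else NULL)

  report <- structure(list(
    config = config,
    config_hash = config_fingerprint(deparse(config[setdiff(
      names(config), "out_dir")])),
    version = tryCatch(
      as.character(utils::packageVersion("speechtrf")),
      error = function(e) NA_character_),
    layout = layout, ground_truth = truth,
    analyzed_subjects = analyzed, exclusions = exclusions,
    epoch_log = do.call(rbind, epoch_log),
    power_table = power_table, anova = anova,
    trf_grand = trf_grand, trf_lags_ms = lags_ms,
    trf_layout = layout_trf, adjacency = adjacency,
    trf_cluster = trf_cluster,
    prediction_clusters = prediction_clusters,
    cv_mean_r = lapply(cv_scores, function(ss)
      if (length(ss)) do.call(rbind, lapply(ss, `[[`, "mean_r"))
      else NULL),
    stimulus = stimulus,
    log = log_lines
  ), class = "run_report")

  if (!is.null(config$out_dir)) write_report_artifacts(report)
  report
}

# Write stage artifacts under config$out_dir (CSV/JSON, text only).
write_report_artifacts <- function(report) {
  dir.create(report$config$out_dir, recursive = TRUE,
             showWarnings = FALSE)
  pth <- function(f) file.path(report$config$out_dir, f)
  data.table::fwrite(report$power_table, pth("power_table.csv"))
  if (!is.null(report$anova))
    data.table::fwrite(as.data.frame(report$anova), pth("anova.csv"))
  data.table::fwrite(report$epoch_log, pth("epoch_log.csv"))
  if (nrow(report$exclusions))
    data.table::fwrite(report$exclusions, pth("exclusions.csv"))
  for (reg in names(report$trf_grand))
    if (!is.null(report$trf_grand[[reg]]))
      write_trf_csv(report$trf_grand[[reg]],
                    pth(sprintf("trf_grand_%s.csv", reg)))
  if (!is.null(report$trf_cluster))
    write_clusters_json(report$trf_cluster, pth("trf_clusters.json"))
  for (reg in names(report$prediction_clusters))
    if (!is.null(report$prediction_clusters[[reg]]))
      write_clusters_json(report$prediction_clusters[[reg]],
                          pth(sprintf("prediction_clusters_%s.json", reg)))
  writeLines(c(sprintf("speechtrf run (version %s, config %s)",
                       report$version, report$config_hash),
               "", "parameters:",
               paste0("  ", format_config(report$config)),
               "", "stages:", paste0("  ", report$log)),
             pth("run_log.txt"))
  invisible(report)
}

format_config <- function(config) {
  vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm,
            if (is.null(v)) "NULL" else paste(deparse(v), collapse = ""))
  }, "")
}

#' Summarize a pipeline run
#'
#' Human-readable summary of a [run_pipeline()] report -- subject
#' accounting, epoch retention, the ANOVA table, significant clusters
#' per test and the descriptive stimulus statistics -- printed to the
#' console, with the same content returned as a JSON string (lossless
#' round-trip via `jsonlite`).
#'
#' @param report a `run_report`.
#' @param quiet suppress printing.
#' @return invisibly, the JSON summary string.
#' @export
report_summary <- function(report, quiet = FALSE) {
  stopifnot(inherits(report, "run_report"))
  cl_desc <- function(res) {
    if (is.null(res)) return(list(n_significant = 0, clusters = list()))
    sig <- Filter(function(cl) isTRUE(cl$significant), res$clusters)
    list(n_significant = length(sig),
         clusters = lapply(sig, function(cl) list(
           sign = cl$sign, mass_t = cl$mass_t, p = cl$p,
           n_points = nrow(cl$members),
           channels = unique(cl$channels))))
  }
  js <- list(
    version = report$version, config_hash = report$config_hash,
    n_analyzed = length(report$analyzed_subjects),
    n_excluded = nrow(report$exclusions),
    exclusions = report$exclusions,
    epochs_kept = if (!is.null(report$epoch_log))
      sum(report$epoch_log$kept) else 0,
    epochs_rejected = if (!is.null(report$epoch_log))
      sum(report$epoch_log$rejected) else 0,
    anova = if (!is.null(report$anova)) as.data.frame(report$anova)
            else NULL,
    trf_cluster = cl_desc(report$trf_cluster),
    prediction_clusters = lapply(report$prediction_clusters, cl_desc),
    speech_rate_wps = as.list(report$stimulus$speech_rate),
    vowel_area_hz2 = as.list(report$stimulus$vowel_area))
  if (!quiet) {
    cat(sprintf("speechtrf run summary (config %s)\n", report$config_hash))
    cat(sprintf("  subjects analyzed: %d, excluded: %d\n",
                js$n_analyzed, js$n_excluded))
    if (js$n_excluded > 0)
      for (i in seq_len(nrow(report$exclusions)))
        cat(sprintf("    subject %d excluded: %s\n",
                    report$exclusions$subject[i],
                    report$exclusions$reason[i]))
    cat(sprintf("  epochs kept/rejected: %d/%d\n", js$epochs_kept,
                js$epochs_rejected))
    if (!is.null(report$anova)) print(report$anova)
    for (nm in c("IDS", "ADS")) {
      d <- js$prediction_clusters[[nm]]
      if (d$n_significant == 0)
        cat(sprintf("  %s prediction: no significant clusters\n", nm))
      else
        cat(sprintf("  %s prediction: %d significant cluster(s), min p = %.4f\n",
                    nm, d$n_significant,
                    min(vapply(d$clusters, `[[`, 0, "p"))))
    }
    d <- js$trf_cluster
    if (d$n_significant == 0)
      cat("  TRF IDS-ADS difference: no significant clusters\n")
    else
      cat(sprintf("  TRF IDS-ADS difference: %d significant cluster(s), min p = %.4f\n",
                  d$n_significant, min(vapply(d$clusters, `[[`, 0, "p"))))
    cat(sprintf("  speech rate (words/s): IDS %.2f, ADS %.2f\n",
                js$speech_rate_wps$IDS, js$speech_rate_wps$ADS))
    if (length(js$vowel_area_hz2))
      cat(sprintf("  vowel-space area (Hz^2): %s\n",
                  paste(sprintf("%s %.2f", names(js$vowel_area_hz2),
                                unlist(js$vowel_area_hz2)),
                        collapse = ", ")))
  }
  invisible(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA,
                             null = "null"))
}

#' @export
print.run_report <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
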