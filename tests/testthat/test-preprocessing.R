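test_that("ASR calibration tracks homogeneous data and excludes burst windows", {
  lay <- tiny_layout(12)
  set.seed(10)
  x <- matrix(rnorm(128 * 60 * 12, sd = 5), ncol = 12)
  rec <- eeg_recording(x, 128, lay)
  m <- asr_calibrate(rec, window_len = 500, clean_fraction = 0.5)
  # per-direction calibration variance close to the sample covariance
  ev_cal <- eigen(m$calibration_cov, symmetric = TRUE)$values
  ev_all <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(ev_cal, ev_all, tolerance = 0.05)
  expect_identical(m, asr_calibrate(rec, 500, 0.5))
  expect_error(asr_calibrate(eeg_recording(x[1:200, ], 128, lay), 500),
               "calibrate")

  # 10% of windows carry huge bursts; calibration must ignore them
  xb <- x
  burst_win <- seq(5, 55, by = 10)          # seconds
  w <- 64                                   # 500 ms at 128 Hz
  burst_rows <- unlist(lapply(burst_win, function(s0)
    (s0 * 128 + 1):(s0 * 128 + w)))
  xb[burst_rows, ] <- xb[burst_rows, ] * 50
  recb <- eeg_recording(xb, 128, lay)
  mb <- asr_calibrate(recb, 500, clean_fraction = 0.5)
  rms_cal <- sqrt(mean(diag(mb$calibration_cov)))
  rms_clean <- sqrt(mean(x[-burst_rows, ]^2))
  expect_equal(rms_cal, rms_clean, tolerance = 0.1)
})

test_that("ASR passes clean data through and repairs an injected spatial burst", {
  lay <- tiny_layout(12)
  set.seed(11)
  n <- 128 * 40
  clean <- matrix(rnorm(n * 12, sd = 5), ncol = 12)
  rec <- eeg_recording(clean, 128, lay)
  model <- asr_calibrate(rec, 500, 0.5, threshold_sd = 20)
  out <- asr_clean(rec, model)
  expect_identical(dim(out$data), dim(rec$data))
  expect_lt(max(abs(out$data - rec$data)) / sd(clean), 1e-3)
  # unreachable threshold: output identical to input
  model_hi <- asr_calibrate(rec, 500, 0.5, threshold_sd = 1e9)
  expect_equal(asr_clean(rec, model_hi)$data, rec$data,
               tolerance = 1e-12, ignore_attr = TRUE)

  # 50x burst confined to one spatial direction, 10 seeds
  for (s in 1:10) {
    set.seed(100 + s)
    cl <- matrix(rnorm(n * 12, sd = 5), ncol = 12)
    dir <- rnorm(12); dir <- dir / sqrt(sum(dir^2))
    corrupt <- cl
    rows <- 2000:2255
    corrupt[rows, ] <- corrupt[rows, ] +
      outer(rnorm(length(rows), sd = 50 * 5), dir)
    rc <- eeg_recording(corrupt, 128, lay)
    mdl <- asr_calibrate(rc, 500, 0.5, threshold_sd = 20)
    cleaned <- asr_clean(rc, mdl)
    cor_clean <- cor(as.vector(cleaned$data[rows, ]),
                     as.vector(cl[rows, ]))
    cor_corrupt <- cor(as.vector(corrupt[rows, ]),
                       as.vector(cl[rows, ]))
    expect_gt(cor_clean, cor_corrupt)
  }
})

test_that("bad-channel interpolation uses normalized inverse-distance weights", {
  lay <- tiny_layout(12)
  x <- matrix(rnorm(128 * 12 * 12), ncol = 12)
  # constant field: interpolation must reproduce the constant
  xc <- matrix(7.5, 256, 12)
  q <- rep("good", 12); q[4] <- "bad"
  xc[, 4] <- 999
  rec <- eeg_recording(xc, 128, lay, quality = q)
  out <- interpolate_bad_channels(rec, 6)
  expect_equal(out$data[, 4], rep(7.5, 256), tolerance = 1e-12)
  expect_identical(out$quality[4], "good")

  # hand-worked weights at distances 1, 2, 2 -> 0.5, 0.25, 0.25
  d <- c(1, 2, 2)
  w <- (1 / d) / sum(1 / d)
  expect_equal(w, c(0.5, 0.25, 0.25))
  # weights always sum to 1: linear in channel values, affine-exact
  rec2 <- eeg_recording(x + 3, 128, lay, quality = q)
  rec3 <- eeg_recording(x, 128, lay, quality = q)
  o2 <- interpolate_bad_channels(rec2, 5)
  o3 <- interpolate_bad_channels(rec3, 5)
  expect_equal(o2$data[, 4], o3$data[, 4] + 3, tolerance = 1e-10)
  q_all <- rep("bad", 12)
  expect_error(
    interpolate_bad_channels(eeg_recording(x, 128, lay, quality = q_all)),
    "all channels")
})

test_that("average referencing zeroes row means, is idempotent and matches the subtraction oracle", {
  lay <- tiny_layout(10)
  set.seed(12)
  x <- matrix(rnorm(500 * 10, sd = 20), ncol = 10)
  rec <- eeg_recording(x, 250, lay, reference = "vertex")
  out <- rereference_average(rec)
  expect_lt(max(abs(rowMeans(out$data))), 1e-10)
  expect_identical(out$reference, "average")
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-12)
  expect_equal(out$data, x - rowMeans(x), ignore_attr = TRUE)
  # commutes with common channel scaling
  out_scaled <- rereference_average(eeg_recording(3 * x, 250, lay))
  expect_equal(out_scaled$data, 3 * out$data, tolerance = 1e-12)
})

test_that("resampling preserves in-band tones and DC while removing out-of-band content", {
  lay <- tiny_layout(8)
  t1k <- (0:(1000 * 10 - 1)) / 1000
  tone6 <- sin(2 * pi * 6 * t1k)
  rec <- eeg_recording(matrix(tone6, ncol = 1)[, rep(1, 8)], 1000, lay)
  out <- resample_recording(rec, 250)
  expect_equal(nrow(out$data), floor(10000 * 250 / 1000),
               ignore_attr = TRUE)
  amp <- function(x, fs, f) {
    X <- Mod(stats::fft(x)) / length(x) * 2
    f_axis <- (seq_along(x) - 1) * fs / length(x)
    max(X[abs(f_axis - f) < 0.5])
  }
  expect_equal(amp(out$data[, 1], 250, 6), 1, tolerance = 0.02)
  # 200 Hz tone must vanish at 128 Hz (aliased band fully attenuated)
  tone200 <- sin(2 * pi * 200 * t1k)
  rec2 <- eeg_recording(matrix(tone200, ncol = 1)[, rep(1, 8)], 1000, lay)
  out2 <- resample_recording(rec2, 128)
  expect_lt(sd(out2$data[, 1]) / sd(tone200), 0.01)
  # DC preserved exactly
  recdc <- eeg_recording(matrix(4.2, 1000, 8), 1000, lay)
  expect_equal(unique(round(resample_recording(recdc, 125)$data[, 1], 9)),
               4.2)
  expect_error(resample_recording(rec, 1000), "below")
})

test_that("periphery removal drops exactly the flagged channels in order", {
  lay <- make_layout(128, seed = 7)
  x <- matrix(rnorm(100 * 128), ncol = 128)
  rec <- eeg_recording(x, 128, lay)
  out <- drop_periphery(rec)
  expect_identical(ncol(out$data), 128L - sum(lay$periphery))
  keep <- which(!lay$periphery)
  expect_identical(out$layout$channel_names, lay$channel_names[keep])
  expect_identical(out$data, x[, keep, drop = FALSE],
                   ignore_attr = TRUE)
  expect_equal(out$data, x[, keep], ignore_attr = TRUE)
  # no flags -> identity
  lay0 <- lay; lay0$periphery[] <- FALSE
  rec0 <- eeg_recording(x, 128, lay0)
  expect_identical(drop_periphery(rec0), rec0)
})

test_that("epoch rejection applies the amplitude rule and matches burst ground truth", {
  lay <- tiny_layout(8)
  set.seed(13)
  x <- matrix(rnorm(250 * 20 * 8, sd = 10), ncol = 8)  # all within 100 whp
  x[abs(x) > 95] <- 0
  rec <- eeg_recording(x, 250, lay)
  es <- epoch_and_reject(rec, 1, 100)
  expect_identical(es$rejected_count, 0L)
  expect_identical(es$kept_count, 20L)
  # one 150 uV sample rejects exactly its epoch
  x2 <- x; x2[250 * 4 + 10, 3] <- 150
  es2 <- epoch_and_reject(eeg_recording(x2, 250, lay), 1, 100)
  expect_identical(es2$rejected_idx, 5L)
  # invariance to epoch-internal sample order
  x3 <- x2
  for (ep in 1:20) {
    rows <- ((ep - 1) * 250 + 1):(ep * 250)
    x3[rows, ] <- x2[sample(rows), ]
  }
  es3 <- epoch_and_reject(eeg_recording(x3, 250, lay), 1, 100)
  expect_identical(es3$kept_idx, es2$kept_idx)
  expect_error(epoch_and_reject(rec, 0), "epoch_len")

  # generator bursts: epochs with solid burst overlap are rejected and
  # every rejected epoch overlaps some burst
  s <- sim_small(duration = 60, fs = 128, n_channels = 16, seed = 21,
                 artifact_rate = 6, snr_db = 0)
  es4 <- epoch_and_reject(s$rec, 1, 100)
  bursts <- attr(s$rec, "artifacts")$bursts
  overlap <- function(ep, margin = 0) {
    any(bursts$start_s < ep - margin & bursts$end_s > ep - 1 + margin)
  }
  solid <- which(vapply(seq_len(60), overlap, TRUE, margin = 0.05))
  any_ov <- which(vapply(seq_len(60), overlap, TRUE, margin = 0))
  expect_true(all(solid %in% es4$rejected_idx))
  expect_true(all(es4$rejected_idx %in% any_ov))
})
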