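test_that("envelope extraction recovers a known AM modulator and obeys the length rule", {
  fs_a <- 1000
  t <- (0:(20 * fs_a - 1)) / fs_a
  # constant-envelope tone: 1-8 Hz band-pass leaves ~nothing
  tone <- sin(2 * pi * 100 * t)
  e0 <- extract_envelope(tone, fs_a, c(1, 8), 128)
  core <- e0$values[129:(length(e0$values) - 128)]  # skip filter edges
  expect_lt(sd(core), 0.02)
  # AM tone: extracted modulator matches 0.5 cos(2 pi 4 t)
  am <- (1 + 0.5 * cos(2 * pi * 4 * t)) * cos(2 * pi * 100 * t)
  e <- extract_envelope(am, fs_a, c(1, 8), 128)
  mod <- 0.5 * cos(2 * pi * 4 * (seq_along(e$values) - 1) / 128)
  expect_gt(cor(e$values, mod), 0.95)
  p <- Mod(stats::fft(e$values - mean(e$values)))^2
  f <- (seq_along(p) - 1) * 128 / length(p)
  expect_equal(f[which.max(p[f <= 64])], 4, tolerance = 0.11)
  # length rule floor(n * fs_out / fs_in)
  x10 <- rnorm(10 * 16000)
  e10 <- extract_envelope(x10, 16000, c(1, 8), 128)
  expect_equal(length(e10$values), floor(10 * 128), ignore_attr = TRUE)
  expect_error(extract_envelope(rnorm(100), 1000), "3 filter lengths")
})

test_that("the lagged design matches a brute-force double loop and impulse structure", {
  set.seed(40)
  env <- rnorm(50)
  fs <- 100
  lags <- trf_lags(fs, 0, 80)
  X <- build_lagged_design(env, fs, lags)
  sh <- round(lags * fs / 1000)
  B <- matrix(0, 50, length(sh) + 1)
  B[, ncol(B)] <- 1
  for (j in seq_along(sh)) for (tt in 1:50)
    if (tt - sh[j] >= 1) B[tt, j] <- env[tt - sh[j]]
  expect_equal(X, B, ignore_attr = TRUE)
  expect_equal(X[, 1], env)                 # lag-0 column
  # unit impulse: column j nonzero only at t0 + lag_j
  imp <- numeric(50); imp[10] <- 1
  Xi <- build_lagged_design(imp, fs, lags)
  for (j in seq_along(sh))
    expect_equal(which(Xi[, j] != 0), 10 + sh[j], ignore_attr = TRUE)
  expect_error(build_lagged_design(rnorm(10), 1000, c(0, 500)), "exceed")
})

test_that("ridge TRFs equal the normal equations, shrink to zero and are scale-equivariant", {
  lay <- tiny_layout(8)
  set.seed(41)
  env <- rnorm(400)
  y <- matrix(rnorm(400 * 8), ncol = 8)
  rec <- eeg_recording(y, 100, lay)
  lags <- trf_lags(100, 0, 70)
  m <- fit_trf(env, rec, lambda = 2.5, lags_ms = lags)
  X <- build_lagged_design(env, 100, lags)
  XtX <- crossprod(X)
  k <- length(lags)
  mu <- mean(diag(XtX)[1:k])
  W <- solve(XtX + diag(c(rep(2.5 * mu, k), 0)), crossprod(X, y))
  expect_equal(rbind(m$weights, m$intercept), W, ignore_attr = TRUE,
               tolerance = 1e-10)
  # infinite shrinkage
  mbig <- fit_trf(env, rec, lambda = 1e12, lags_ms = lags)
  expect_lt(max(abs(mbig$weights)), 1e-6 * sd(y))
  # scale equivariance: doubling both sides leaves weights unchanged
  m2 <- fit_trf(2 * env, eeg_recording(2 * y, 100, lay), lambda = 2.5,
                lags_ms = lags)
  expect_equal(m2$weights, m$weights, tolerance = 1e-10)
  expect_error(fit_trf(rep(1, 400), rec), "zero variance")

  # noise-free simulation: weights recover the kernel to < 1%
  s <- sim_small(duration = 90, snr_db = Inf, seed = 3)
  mrec <- fit_trf(s$env, s$rec, lambda = 1e-6)
  expect_lt(max(abs(mrec$weights - s$truth$kernel)) /
              max(abs(s$truth$kernel)), 0.01)
})

test_that("cross-validation partitions time, nails the noise-free limit and is null-calibrated", {
  s <- sim_small(duration = 60, snr_db = Inf, seed = 4, n_channels = 8)
  cv <- crossval_predict(s$env, s$rec, lambda = 1e-6)
  # folds form a partition
  bounds <- do.call(rbind, cv$folds)
  expect_equal(bounds[1, 1], 1, ignore_attr = TRUE)
  expect_equal(bounds[5, 2], nrow(s$rec$data), ignore_attr = TRUE)
  expect_true(all(bounds[-1, 1] == bounds[-5, 2] + 1))
  expect_true(all(cv$mean_r > 0.99))
  # uncoupled: grand-mean r over 20 seeds within the simulated null band
  rs <- numeric(20)
  for (i in 1:20) {
    s0 <- sim_small(duration = 60, coupling_gain = 0, seed = i,
                    n_channels = 8)
    rs[i] <- mean(crossval_predict(s0$env, s0$rec, lambda = 1)$mean_r)
  }
  expect_lt(abs(mean(rs)), 2 / sqrt(60 * 128))
  expect_error(crossval_predict(s$env, s$rec, n_folds = 50), "10 s")
})

test_that("cross-validated prediction degrades with noise and tracks register coupling", {
  # monotone in noise: 4 SNR levels x 10 seeds
  mean_r <- matrix(0, 4, 10)
  snrs <- c(10, 3, -3, -10)
  for (j in 1:10) for (i in 1:4) {
    s <- sim_small(duration = 60, snr_db = snrs[i], seed = 60 + j,
                   n_channels = 8)
    mean_r[i, j] <- mean(crossval_predict(s$env, s$rec, 1)$mean_r)
  }
  avg <- rowMeans(mean_r)
  expect_true(all(diff(avg) < 0))
  # IDS (high coupling) beats ADS (low coupling) on every seed
  for (j in 1:5) {
    si <- sim_small(duration = 60, register = "IDS", coupling_gain = 1,
                    seed = 70 + j, n_channels = 16)
    sa <- sim_small(duration = 60, register = "ADS", coupling_gain = 0,
                    seed = 70 + j, n_channels = 16)
    fl <- si$layout$region == "frontal-left"
    ri <- mean(crossval_predict(si$env, si$rec, 1)$mean_r[fl])
    ra <- mean(crossval_predict(sa$env, sa$rec, 1)$mean_r[fl])
    expect_gt(ri, ra)
  }
})

test_that("grand averaging is the element-wise mean", {
  lay <- tiny_layout(8)
  set.seed(42)
  mk <- function() {
    env <- rnorm(200)
    fit_trf(env, eeg_recording(matrix(rnorm(200 * 8), ncol = 8), 100,
                               lay),
            lambda = 1, lags_ms = trf_lags(100, 0, 50))
  }
  ms <- replicate(5, mk(), simplify = FALSE)
  ga <- grand_average_trf(ms)
  expect_equal(ga$weights,
               Reduce(`+`, lapply(ms, `[[`, "weights")) / 5,
               tolerance = 1e-12)
  expect_equal(grand_average_trf(ms[1])$weights, ms[[1]]$weights)
  neg <- ms[[1]]; neg$weights <- -neg$weights; neg$intercept <- -neg$intercept
  expect_equal(max(abs(grand_average_trf(list(ms[[1]], neg))$weights)), 0)
  bad <- ms[[2]]; bad$lag_ms <- bad$lag_ms + 1
  expect_error(grand_average_trf(list(ms[[1]], bad)), "mismatched")
})

test_that("stimulus descriptives reproduce the worked values and the shoelace oracle", {
  expect_equal(speech_rate(1384, 486), 2.85)
  expect_equal(speech_rate(1810, 481), 3.76)
  expect_equal(speech_rate(0, 100), 0)
  expect_error(speech_rate(10, 0), "positive")
  expect_equal(vowel_triangle_area(rbind(c(0, 0), c(2, 0), c(0, 2))), 2)
  expect_equal(vowel_triangle_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  set.seed(43)
  for (i in 1:20) {
    tri <- matrix(runif(6, 100, 3000), 3, 2)
    v1 <- tri[2, ] - tri[1, ]; v2 <- tri[3, ] - tri[1, ]
    oracle <- abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
    expect_equal(vowel_triangle_area(tri), oracle, tolerance = 1e-12)
  }
})
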