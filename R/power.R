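#' Hanning-window power spectrum of an epoch set
#'
#' Discrete Fourier power spectrum with a Hanning window of one epoch's
#' width and 50% overlap, averaged over all segments and expressed per
#' frequency bin (bin spacing `1/epoch_len` Hz, i.e. 1 Hz for 1-s
#' epochs). Overlapping segments are formed only within runs of
#' *contiguous* kept epochs, so no segment straddles a rejected epoch.
#' The window is energy-normalized: for a stationary signal the summed
#' per-bin power matches the time-domain variance (Parseval).
#'
#' @param epochs an [epoch_and_reject()] `epoch_set` with at least one
#'   kept epoch.
#' @return object of class `eeg_psd`: `power` (frequency bins x
#'   channels, uV^2 per bin), `freq` (Hz), `n_segments`, `layout`.
#' @export
power_spectrum <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$kept_count < 1) stop("no kept epochs", call. = FALSE)
  L <- dim(epochs$epochs)[1]
  p <- dim(epochs$epochs)[2]
  hop <- L %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)   # periodic Hanning
  u <- sum(win^2)

  # contiguous runs of kept epochs -> one concatenated record per run
  kept <- epochs$kept_idx
  runs <- split(seq_along(kept), cumsum(c(1, diff(kept) != 1)))
  acc <- matrix(0, L %/% 2 + 1, p)
  n_seg <- 0
  for (r in runs) {
    xr <- matrix(aperm(epochs$epochs[, , r, drop = FALSE], c(1, 3, 2)),
                 nrow = L * length(r), ncol = p)
    starts <- seq(1, nrow(xr) - L + 1, by = hop)
    for (s0 in starts) {
      seg <- xr[s0:(s0 + L - 1), , drop = FALSE] * win
      X <- mvfft(seg)[seq_len(L %/% 2 + 1), , drop = FALSE]
      pw <- Mod(X)^2 / (u * L)        # uV^2 per bin (energy-normalized)
      pw[2:(L %/% 2), ] <- 2 * pw[2:(L %/% 2), ]      # one-sided doubling
      acc <- acc + pw
      n_seg <- n_seg + 1
    }
  }
  structure(list(power = acc / n_seg,
                 freq = (0:(L %/% 2)) / epochs$epoch_len,
                 n_segments = n_seg, layout = epochs$layout),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d bins (0-%g Hz) x %d channels, %d segments\n",
              length(x$freq), max(x$freq), ncol(x$power), x$n_segments))
  invisible(x)
}

#' Band power per frontal region
#'
#' Averages spectral power over the bins of a frequency band (inclusive
#' edges) and over the channels of each frontal region of the layout,
#' yielding one value per region -- the quantity entering the register x
#' hemisphere comparison.
#'
#' @param psd an [power_spectrum()] `eeg_psd`.
#' @param band two-element Hz interval, default the theta band `c(4, 8)`.
#' @param layout layout to take region labels from (defaults to the
#'   psd's own).
#' @return data.frame with columns `region` and `power` (uV^2).
#' @export
band_region_power <- function(psd, band = c(4, 8), layout = psd$layout) {
  stopifnot(inherits(psd, "eeg_psd"), length(band) == 2)
  if (band[2] > max(psd$freq) || band[1] < 0)
    stop("band outside the spectral range", call. = FALSE)
  bins <- which(psd$freq >= band[1] & psd$freq <= band[2])
  out <- lapply(c("frontal-left", "frontal-right"), function(rg) {
    ch <- which(layout$region == rg)
    if (length(ch) == 0)
      stop(sprintf("region %s has no channels", rg), call. = FALSE)
    data.frame(region = rg,
               power = mean(psd$power[bins, ch, drop = FALSE]))
  })
  do.call(rbind, out)
}

#' Two-way repeated-measures ANOVA (register x hemisphere)
#'
#' Within-subjects ANOVA for the 2 x 2 design with factors register
#' (IDS/ADS) and hemisphere (frontal-left/frontal-right), fitted with
#' `stats::aov` using an `Error(subject/(register*hemisphere))` stratum
#' structure. Each effect is tested with 1 and n-1 degrees of freedom;
#' effect size is reported as partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table data.frame with columns `subject`, `register`, `region`
#'   (or `hemisphere`) and `theta_power` (or `power`), one complete 2 x 2
#'   cell set per subject.
#' @return data.frame of class `rm_anova`: one row per effect with `F`,
#'   `df_num`, `df_den`, `p`, `eta_sq`.
#' @export
rm_anova_2x2 <- function(table) {
  d <- as.data.frame(table)
  if (!"hemisphere" %in% names(d)) d$hemisphere <- d$region
  if (!"theta_power" %in% names(d)) d$theta_power <- d$power
  d$subject <- factor(d$subject)
  d$register <- factor(d$register)
  d$hemisphere <- factor(d$hemisphere)
  if (nlevels(d$register) != 2 || nlevels(d$hemisphere) != 2)
    stop("register and hemisphere must each have two levels", call. = FALSE)
  counts <- table(d$subject, d$register, d$hemisphere)
  if (any(counts != 1))
    stop("design incomplete: need exactly one row per subject x register x hemisphere",
         call. = FALSE)
  fit <- aov(theta_power ~ register * hemisphere +
               Error(subject / (register * hemisphere)), data = d)
  s <- summary(fit)
  pick <- function(stratum, effect) {
    tab <- s[[stratum]][[1]]
    i <- grep(effect, trimws(rownames(tab)), fixed = TRUE)[1]
    ssr <- tab[grep("Residuals", rownames(tab)), "Sum Sq"]
    data.frame(effect = effect,
               F = tab[i, "F value"],
               df_num = tab[i, "Df"],
               df_den = tab[grep("Residuals", rownames(tab)), "Df"],
               p = tab[i, "Pr(>F)"],
               eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ssr))
  }
  out <- rbind(pick("Error: subject:register", "register"),
               pick("Error: subject:hemisphere", "hemisphere"),
               pick("Error: subject:register:hemisphere",
                    "register:hemisphere"))
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-22s F(%d,%d) = %.2f, p = %.4f, partial eta^2 = %.2f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i],
                x$eta_sq[i]))
  invisible(x)
}
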