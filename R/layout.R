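#' Idealized high-density EEG sensor layout
#'
#' Builds a mirror-symmetric spherical electrode layout in the spirit of a
#' high-density geodesic sensor net: a vertex electrode plus rings of
#' electrodes at increasing polar angle, extending below the equator as
#' real infant nets do. Channels are labelled by scalp region
#' (`frontal-left`, `frontal-right`, `other`) and the lowest-lying channels
#' are flagged as periphery (face/neck electrodes that are conventionally
#' discarded before TRF analysis). Vendor coordinates are not reproduced;
#' only adjacency and region membership matter downstream.
#'
#' Coordinates use +x = right, +y = anterior, +z = superior, all on the
#' unit sphere. The layout is exactly mirror-symmetric about the sagittal
#' (x = 0) plane, so left/right region counts are equal by construction.
#' For layouts of 64 channels or more at least 21 channels carry the
#' periphery flag, mirroring the 21 peripheral electrodes removed from a
#' 129-channel net.
#'
#' @param n_channels number of electrodes (>= 8), vertex included.
#' @param seed integer seed; controls the small symmetric azimuthal jitter.
#' @return an object of class `eeg_layout`: list with `channel_names`,
#'   `positions` (n x 3), `region` (factor), `periphery` (logical),
#'   `reference_channel`.
#' @examples
#' lay <- make_layout(32, seed = 1)
#' table(lay$region)
#' @export
make_layout <- function(n_channels, seed = 1) {
  if (n_channels < 8) stop("n_channels must be >= 8", call. = FALSE)
  n_rest <- n_channels - 1          # vertex electrode sits at the pole
  theta_max <- 2.2                  # rad; net extends ~35 deg below equator
  n_rings <- max(2, round(sqrt(n_rest / 1.8)))
  th <- theta_max * seq_len(n_rings) / n_rings
  raw <- sin(th) / sum(sin(th)) * n_rest
  counts <- pmax(2, 2 * round(raw / 2))         # even per ring -> symmetric
  # adjust ring counts (by +/-2, keeping them even) until they sum to
  # n_rest or n_rest - 1; a single leftover goes on the sagittal midline
  repeat {
    excess <- sum(counts) - n_rest
    if (excess %in% c(0, -1)) break
    if (excess > 0) {
      i <- which.max(counts)
      counts[i] <- counts[i] - 2
    } else {
      i <- which.max(raw - counts)
      counts[i] <- counts[i] + 2
    }
  }
  midline_extra <- n_rest - sum(counts)

  pos <- matrix(0, 0, 3)
  jit <- with_seed(seed, lapply(counts, function(m) runif(m, -0.25, 0.25)))
  for (k in seq_len(n_rings)) {
    m <- counts[k]
    base <- (seq_len(m) - 0.5) * 2 * pi / m
    # jitter applied pair-wise so mirror symmetry about x = 0 is preserved:
    # the mirror partner of azimuth phi is pi - phi
    right <- base[cos(base) > 1e-9]              # x > 0 half
    mid <- base[abs(cos(base)) <= 1e-9]          # points on the midline
    dj <- jit[[k]][seq_along(right)] * 2 * pi / m
    right <- right + dj
    phi <- c(right, pi - right, mid)
    ring <- cbind(sin(th[k]) * cos(phi), sin(th[k]) * sin(phi),
                  rep(cos(th[k]), length(phi)))
    pos <- rbind(pos, ring)
  }
  if (midline_extra == 1) {
    thm <- theta_max * 0.45                      # mid-frontal midline site
    pos <- rbind(pos, c(0, sin(thm), cos(thm)))
  }
  pos <- rbind(c(0, 0, 1), pos)                  # vertex first
  pos <- pos / sqrt(rowSums(pos^2))

  region <- rep("other", n_channels)
  frontal <- pos[, 2] > 0.35 & pos[, 3] > 0.10
  region[frontal & pos[, 1] < -0.05] <- "frontal-left"
  region[frontal & pos[, 1] > 0.05] <- "frontal-right"

  n_periph <- if (n_channels >= 64) max(21L, round(n_channels * 21 / 129))
              else max(2L, round(n_channels / 6))
  periphery <- rep(FALSE, n_channels)
  periphery[order(pos[, 3])[seq_len(n_periph)]] <- TRUE

  names_ <- c("Cz", paste0("E", seq_len(n_channels - 1)))
  structure(list(
    channel_names = names_,
    positions = pos,
    region = factor(region,
                    levels = c("frontal-left", "frontal-right", "other")),
    periphery = periphery,
    reference_channel = "Cz"
  ), class = "eeg_layout")
}

#' @export
print.eeg_layout <- function(x, ...) {
  cat(sprintf("<eeg_layout> %d channels (reference %s)\n",
              length(x$channel_names), x$reference_channel))
  print(table(region = x$region))
  cat(sprintf("periphery-flagged: %d\n", sum(x$periphery)))
  invisible(x)
}

# Subset a layout to a channel index vector, preserving order.
layout_subset <- function(layout, idx) {
  structure(list(
    channel_names = layout$channel_names[idx],
    positions = layout$positions[idx, , drop = FALSE],
    region = layout$region[idx],
    periphery = layout$periphery[idx],
    reference_channel = layout$reference_channel
  ), class = "eeg_layout")
}
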