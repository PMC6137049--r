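#' Spatial adjacency from a sensor layout
#'
#' Two channels are neighbours iff their great-circle distance on the
#' unit sphere is at most `max_dist`. The default radius is 1.6 times the
#' layout's median nearest-neighbour distance, which yields a mean
#' neighbour count of roughly 4-8 on high-density layouts.
#'
#' @param layout an [make_layout()] layout with >= 2 channels.
#' @param max_dist neighbourhood radius in radians (> 0), or `NULL` for
#'   the geometric default.
#' @return object of class `eeg_adjacency`: `neighbors` (list of integer
#'   vectors, symmetric, no self-neighbours), `max_dist`,
#'   `channel_names`.
#' @export
build_adjacency <- function(layout, max_dist = NULL) {
  stopifnot(inherits(layout, "eeg_layout"),
            length(layout$channel_names) >= 2)
  d <- gc_dist(layout$positions)
  if (is.null(max_dist)) {
    diag(d) <- Inf
    max_dist <- 1.6 * median(apply(d, 1, min))
    diag(d) <- 0
  }
  if (max_dist <= 0) stop("max_dist must be positive", call. = FALSE)
  p <- nrow(d)
  nb <- lapply(seq_len(p), function(i)
    setdiff(which(d[i, ] <= max_dist), i))
  structure(list(neighbors = nb, max_dist = max_dist,
                 channel_names = layout$channel_names),
            class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  cat(sprintf("<eeg_adjacency> %d channels, radius %.3f rad, mean degree %.2f\n",
              length(x$neighbors), x$max_dist,
              mean(lengths(x$neighbors))))
  invisible(x)
}

#' Pointwise t-statistics across subjects
#'
#' Computes a t-map over (electrode, time) points: a paired t on the
#' condition difference when `data_b` is supplied with `paired = TRUE`,
#' a Welch two-sample t when `paired = FALSE`, or a one-sample t against
#' zero when `data_b` is `NULL` (e.g. prediction correlations).
#' Degenerate points (zero variance) yield `NA` and are excluded from
#' clustering.
#'
#' @param data_a numeric array, subjects x electrodes (x time).
#' @param data_b matching array for the second condition, or `NULL`.
#' @param paired logical; condition labels are exchangeable within
#'   subject.
#' @return list with `t` (electrodes x time matrix), `df`, `n`.
#' @export
pointwise_t <- function(data_a, data_b = NULL, paired = TRUE) {
  a <- as_subj_array(data_a)
  if (dim(a)[1] < 3) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(data_b) || paired) {
    if (!is.null(data_b)) {
      b <- as_subj_array(data_b)
      if (!all(dim(a) == dim(b)))
        stop("paired conditions must share subjects and dimensions",
             call. = FALSE)
      a <- a - b
    }
    n <- dim(a)[1]
    D <- matrix(a, n)                      # subjects x (e*t)
    m <- colMeans(D)
    v <- (colSums(D^2) - n * m^2) / (n - 1)
    t <- m / sqrt(v / n)
    t[v <= 0] <- NA_real_
    df <- n - 1
  } else {
    b <- as_subj_array(data_b)
    if (!all(dim(a)[-1] == dim(b)[-1]))
      stop("conditions must share electrode/time dimensions", call. = FALSE)
    na <- dim(a)[1]; nb <- dim(b)[1]
    Da <- matrix(a, na); Db <- matrix(b, nb)
    va <- apply(Da, 2, var); vb <- apply(Db, 2, var)
    se2 <- va / na + vb / nb
    t <- (colMeans(Da) - colMeans(Db)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    t[se2 <= 0] <- NA_real_
    df <- mean(df, na.rm = TRUE)
    n <- na
  }
  list(t = matrix(t, dim(a)[2], dim(a)[3]), df = df, n = dim(a)[1])
}

# Coerce subjects x electrodes (x time) input to a 3-d array.
as_subj_array <- function(x) {
  if (length(dim(x)) == 3) return(x)
  x <- as.matrix(x)
  array(x, c(nrow(x), ncol(x), 1))
}

#' Form spatiotemporal clusters from a t-map
#'
#' Thresholds the t-map at the two-sided `cluster_alpha` quantile of the
#' t distribution with `df` degrees of freedom, groups suprathreshold
#' same-sign points by spatial adjacency within each time point, and
#' merges groups across consecutive time points that share at least one
#' electrode. Each cluster's statistic is its mass t-score, the sum of
#' member t-values.
#'
#' @param t_map electrodes x time matrix of t-values (`NA` allowed).
#' @param adjacency an [build_adjacency()] object.
#' @param cluster_alpha two-sided point-level alpha forming the
#'   threshold, default 0.05.
#' @param df degrees of freedom of the pointwise tests.
#' @return list of clusters, each a list with `members` (matrix with
#'   columns `electrode`, `time`), `mass_t`, `sign`; ordered by
#'   decreasing `|mass_t|`. Empty list when nothing is suprathreshold.
#' @export
form_clusters <- function(t_map, adjacency, cluster_alpha = 0.05, df) {
  t_map <- as.matrix(t_map)
  thr <- qt(1 - cluster_alpha / 2, df)
  e <- nrow(t_map); tt <- ncol(t_map)
  supra <- which(!is.na(t_map) & abs(t_map) > thr)
  if (length(supra) == 0) return(list())
  lab <- integer(e * tt)                   # 0 = not suprathreshold
  sgn <- sign(t_map)
  nb <- adjacency$neighbors
  # union-find
  parent <- seq_along(supra)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx_of <- integer(e * tt)
  idx_of[supra] <- seq_along(supra)
  for (s in seq_along(supra)) {
    pt <- supra[s]
    ei <- (pt - 1) %% e + 1
    ti <- (pt - 1) %/% e + 1
    sg <- sgn[ei, ti]
    for (ne in nb[[ei]]) {               # spatial, same time point
      q <- (ti - 1) * e + ne
      if (idx_of[q] > 0 && sgn[ne, ti] == sg) {
        ri <- find(s); rj <- find(idx_of[q])
        if (ri != rj) parent[ri] <- rj
      }
    }
    if (ti > 1) {                        # temporal, same electrode
      q <- (ti - 2) * e + ei
      if (idx_of[q] > 0 && sgn[ei, ti - 1] == sg) {
        ri <- find(s); rj <- find(idx_of[q])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(supra), find, 1L)
  groups <- split(seq_along(supra), roots)
  out <- lapply(groups, function(g) {
    pts <- supra[g]
    ei <- (pts - 1) %% e + 1
    ti <- (pts - 1) %/% e + 1
    mass <- sum(t_map[cbind(ei, ti)])
    list(members = cbind(electrode = ei, time = ti),
         mass_t = mass, sign = if (mass >= 0) "positive" else "negative")
  })
  out[order(-abs(vapply(out, `[[`, 0, "mass_t")))]
}

# Max |mass| over the clusters of one t-map (0 when none); the permutation
# null summary statistic.
max_cluster_mass <- function(t_map, adjacency, cluster_alpha, df) {
  cl <- form_clusters(t_map, adjacency, cluster_alpha, df)
  if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, 0, "mass_t")))
}

#' Cluster-mass permutation test
#'
#' Tests condition differences (paired, label-swap within subject) or a
#' one-sample effect against zero (sign flip per subject) with
#' family-wise error control by cluster-mass permutation: pointwise
#' t-maps are clustered ([form_clusters()]), each permutation's summary
#' is its maximum absolute cluster mass, and every observed cluster's
#' p-value is the (+1-corrected) fraction of permutation summaries at
#' least as large as its own |mass|. A cluster is significant when its
#' mass falls in the top or bottom 2.5th percentile of the null, i.e.
#' p <= alpha with the two-sided max-|mass| null.
#'
#' @param data_a subjects x electrodes (x time) array.
#' @param data_b matching array (paired design) or `NULL` (one-sample).
#' @param adjacency an [build_adjacency()] object.
#' @param n_permutations number of random permutations, >= 100.
#' @param seed integer seed for the permutation draws.
#' @param cluster_alpha point-level threshold alpha, default 0.05.
#' @param alpha cluster-level significance level, default 0.05
#'   (two-sided).
#' @param times optional labels (e.g. lag ms) for the time axis.
#' @return object of class `cluster_result`: `clusters` (each with
#'   `members`, `mass_t`, `p`, `sign`, `significant`), `null_max`
#'   (permutation distribution), `threshold`, `df`, `n_permutations`,
#'   `alpha`.
#' @export
permutation_test <- function(data_a, data_b = NULL, adjacency,
                             n_permutations = 1000, seed = 1,
                             cluster_alpha = 0.05, alpha = 0.05,
                             times = NULL) {
  if (n_permutations < 100)
    stop("n_permutations must be at least 100 for a stable tail",
         call. = FALSE)
  a <- as_subj_array(data_a)
  if (!is.null(data_b)) {
    b <- as_subj_array(data_b)
    if (!all(dim(a) == dim(b)))
      stop("paired conditions must share subjects and dimensions",
           call. = FALSE)
    a <- a - b                        # paired: sign flip of differences
  }
  n <- dim(a)[1]; e <- dim(a)[2]; tt <- dim(a)[3]
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (length(adjacency$neighbors) != e)
    stop("adjacency does not match the electrode dimension", call. = FALSE)
  df <- n - 1
  D <- matrix(a, n)
  ss <- colSums(D^2)
  t_of <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    t <- m / sqrt(v / n)
    t[v <= 1e-300] <- NA_real_
    t
  }
  t_obs <- matrix(t_of(colMeans(D)), e, tt)
  obs <- form_clusters(t_obs, adjacency, cluster_alpha, df)

  S <- with_seed(seed,
    matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
           n_permutations, n))
  M <- (S %*% D) / n
  null_max <- numeric(n_permutations)
  for (i in seq_len(n_permutations))
    null_max[i] <- max_cluster_mass(matrix(t_of(M[i, ]), e, tt),
                                    adjacency, cluster_alpha, df)

  clusters <- lapply(obs, function(cl) {
    p <- (1 + sum(null_max >= abs(cl$mass_t))) / (n_permutations + 1)
    cl$p <- p
    cl$significant <- p <= alpha
    if (!is.null(times)) cl$time_values <- times[cl$members[, "time"]]
    cl$channels <- adjacency$channel_names[cl$members[, "electrode"]]
    cl
  })
  structure(list(clusters = clusters, null_max = null_max,
                 t_map = t_obs, df = df,
                 threshold = qt(1 - cluster_alpha / 2, df),
                 n_permutations = n_permutations, alpha = alpha,
                 times = times),
            class = "cluster_result")
}

#' Spatial cluster test of prediction correlations against zero
#'
#' One-sample, spatial-only specialization of [permutation_test()] for
#' per-subject, per-electrode EEG prediction correlations: sign-flip
#' permutation of the subject-level r values, clustering over electrodes
#' only.
#'
#' @param scores subjects x electrodes matrix of correlations, or a list
#'   of per-subject [crossval_predict()] results (their `mean_r` rows).
#' @inheritParams permutation_test
#' @return a `cluster_result` (time dimension of length 1).
#' @export
prediction_cluster_test <- function(scores, adjacency,
                                    n_permutations = 1000, seed = 1,
                                    cluster_alpha = 0.05, alpha = 0.05) {
  if (is.list(scores) && !is.matrix(scores))
    scores <- do.call(rbind, lapply(scores, `[[`, "mean_r"))
  permutation_test(as.matrix(scores), NULL, adjacency,
                   n_permutations = n_permutations, seed = seed,
                   cluster_alpha = cluster_alpha, alpha = alpha)
}

#' @export
print.cluster_result <- function(x, ...) {
  if (length(x$clusters) == 0) {
    cat("<cluster_result> no suprathreshold clusters\n")
    return(invisible(x))
  }
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_permutations))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: %s, %d points, mass t = %.1f, p = %.4f%s\n",
                i, cl$sign, nrow(cl$members), cl$mass_t, cl$p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}
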