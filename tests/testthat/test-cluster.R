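test_that("adjacency respects the distance rule and the default radius is sensible", {
  lay <- make_layout(128, seed = 7)
  expect_true(all(lengths(build_adjacency(lay, 1e-6)$neighbors) == 0))
  full <- build_adjacency(lay, pi + 0.1)
  expect_true(all(lengths(full$neighbors) == 127))
  adj <- build_adjacency(lay)
  deg <- mean(lengths(adj$neighbors))
  expect_gte(deg, 4); expect_lte(deg, 8)
  # symmetric, no self-neighbours (brute-force check)
  for (i in c(1, 17, 99)) {
    expect_false(i %in% adj$neighbors[[i]])
    for (j in adj$neighbors[[i]]) expect_true(i %in% adj$neighbors[[j]])
  }
  expect_error(build_adjacency(lay, -1), "positive")
})

test_that("pointwise t matches closed forms and flags degenerate points", {
  set.seed(50)
  d <- matrix(rnorm(10 * 6, mean = 2), 10, 6)
  pt <- pointwise_t(d)
  oracle <- apply(d, 2, function(z) unname(t.test(z)$statistic))
  expect_equal(as.vector(pt$t), oracle, tolerance = 1e-10)
  expect_equal(pt$df, 9)
  # constant difference d with SD s: t = d sqrt(n) / s
  a <- matrix(rnorm(12 * 4), 12, 4)
  b <- a - 0.7 - rnorm(12) * 0  # zero-noise shift
  shift <- rnorm(12, 0.7, 0.3)
  b2 <- a - shift
  t_expected <- mean(shift) * sqrt(12) / sd(shift)
  pt2 <- pointwise_t(a, b2, paired = TRUE)
  expect_equal(as.vector(pt2$t), rep(t_expected, 4), tolerance = 1e-10)
  # null: zero mean difference over seeds
  ts <- replicate(200, {
    x <- matrix(rnorm(8 * 3), 8, 3)
    mean(pointwise_t(x)$t)
  })
  expect_lt(abs(mean(ts)), 0.15)
  # all-zero one-sample data -> NA flagged, excluded from clustering
  z <- matrix(0, 6, 4)
  ptz <- pointwise_t(z)
  expect_true(all(is.na(ptz$t)))
  lay <- tiny_layout(8)
  expect_identical(form_clusters(matrix(NA_real_, 8, 2),
                                 build_adjacency(lay, 1), 0.05, 5),
                   list())
  expect_error(pointwise_t(matrix(0, 2, 3)), "3 subjects")
})

test_that("cluster formation follows adjacency, sign and temporal contiguity", {
  lay <- make_layout(9, seed = 1)
  complete <- build_adjacency(lay, pi)
  isolated <- build_adjacency(lay, 1e-6)
  tm <- matrix(0, 9, 4)
  tm[1:3, 2:3] <- 5
  cl <- form_clusters(tm, complete, 0.05, df = 11)
  expect_length(cl, 1)
  expect_identical(nrow(cl[[1]]$members), 6L)
  expect_equal(cl[[1]]$mass_t, 30)
  expect_identical(cl[[1]]$sign, "positive")
  # below threshold: nothing
  expect_length(form_clusters(matrix(1, 9, 4), complete, 0.05, 11), 0)
  # two non-adjacent suprathreshold electrodes: two singletons
  tm2 <- matrix(0, 9, 1); tm2[c(2, 7)] <- 4
  expect_length(form_clusters(tm2, isolated, 0.05, 11), 2)
  # opposite signs never merge even when adjacent
  tm3 <- matrix(0, 9, 1); tm3[1] <- 5; tm3[2] <- -5
  expect_length(form_clusters(tm3, complete, 0.05, 11), 2)
  # temporal merge requires a shared electrode
  tm4 <- matrix(0, 9, 2); tm4[1, 1] <- 5; tm4[2, 2] <- 5
  expect_length(form_clusters(tm4, isolated, 0.05, 11), 2)
  tm4[1, 2] <- 5
  cl4 <- form_clusters(tm4, isolated, 0.05, 11)
  expect_length(cl4, 2)   # {e1,t1;e1,t2} merged; {e2,t2} separate
  expect_identical(unname(sort(vapply(cl4, function(c) nrow(c$members),
                                      1L))),
                   c(1L, 2L))
})

test_that("the permutation test is deterministic, bounded below and order-stable", {
  lay <- tiny_layout(16)
  adj <- build_adjacency(lay)
  set.seed(51)
  r <- matrix(rnorm(12 * 16, 0, 0.03), 12, 16)
  r[, 1:5] <- r[, 1:5] + 0.08
  res1 <- prediction_cluster_test(r, adj, n_permutations = 500, seed = 9)
  res2 <- prediction_cluster_test(r, adj, n_permutations = 500, seed = 9)
  expect_identical(res1$null_max, res2$null_max)
  expect_identical(vapply(res1$clusters, `[[`, 0, "p"),
                   vapply(res2$clusters, `[[`, 0, "p"))
  # p-values bounded below by 1/(n_perm + 1)
  expect_gte(min(vapply(res1$clusters, `[[`, 0, "p")), 1 / 501)
  # permuting subject order leaves the observed clusters identical and
  # the p-values stable to Monte-Carlo resolution
  perm <- sample(12)
  res3 <- prediction_cluster_test(r[perm, ], adj, n_permutations = 500,
                                  seed = 9)
  expect_equal(vapply(res1$clusters, `[[`, 0, "mass_t"),
               vapply(res3$clusters, `[[`, 0, "mass_t"))
  expect_lt(max(abs(vapply(res1$clusters, `[[`, 0, "p") -
                      vapply(res3$clusters, `[[`, 0, "p"))), 0.05)
  expect_error(permutation_test(r, NULL, adj, n_permutations = 50),
               "at least 100")
})

test_that("implanted effects are detected with growing mass and cluster overlap", {
  lay <- tiny_layout(32)
  adj <- build_adjacency(lay)
  fl <- which(lay$region == "frontal-left")
  seedling <- fl[1]
  implant <- c(seedling, adj$neighbors[[seedling]])[1:4]
  implant <- implant[!is.na(implant)]
  # monotonicity: same noise, increasing effect -> non-decreasing mass
  for (s in 1:10) {
    set.seed(200 + s)
    noise <- matrix(rnorm(12 * 32, 0, 0.05), 12, 32)
    masses <- vapply(c(0.05, 0.1, 0.2), function(eff) {
      r <- noise
      r[, implant] <- r[, implant] + eff
      res <- prediction_cluster_test(r, adj, n_permutations = 200,
                                     seed = 1)
      if (length(res$clusters) == 0) 0
      else max(abs(vapply(res$clusters, `[[`, 0, "mass_t")))
    }, 0)
    expect_true(all(diff(masses) >= 0))
  }
})

test_that("an elevated frontal patch of prediction correlations is recovered", {
  lay <- tiny_layout(32)
  adj <- build_adjacency(lay)
  fl <- which(lay$region %in% c("frontal-left", "frontal-right"))
  seedling <- fl[1]
  implant <- unique(c(seedling, adj$neighbors[[seedling]],
                      unlist(lapply(adj$neighbors[[seedling]],
                                    function(j) adj$neighbors[[j]]))))
  implant <- intersect(implant, seq_len(32))[1:8]
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    r <- matrix(rnorm(12 * 32, 0, 0.02), 12, 32)
    r[, implant] <- r[, implant] + 0.05
    res <- prediction_cluster_test(r, adj, n_permutations = 300,
                                   seed = s)
    sig <- significant_clusters(res)
    ok <- any(vapply(sig, function(cl)
      length(intersect(cl$members[, "electrode"], implant)) >= 6, TRUE))
    hits <- hits + ok
  }
  expect_gte(hits, 18)
  # all-equal positive r: a single all-electrode cluster
  rconst <- matrix(0.2, 12, 32) + matrix(rnorm(12 * 32, 0, 1e-4), 12, 32)
  resc <- prediction_cluster_test(rconst, adj, n_permutations = 200,
                                  seed = 3)
  expect_identical(nrow(resc$clusters[[1]]$members), 32L)
})
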