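# Pattern preprocessing, k-means++, G-means, spatial maps.

test_that("binning and masking identities hold", {
  shape <- c(16L, 16L)
  ones <- make_sparse_scan(list(matrix(1, 16, 16)), c(1, 1))
  # bin 1, no mask: features equal the raw dense frame
  f1 <- preprocess_patterns(ones, bin_factor = 1, mask_radius = 0)
  expect_equal(matrix(f1$features[1, ], 16, 16), matrix(1, 16, 16))
  # 8x8 binning of a frame of ones: every binned pixel is 64
  f8 <- preprocess_patterns(ones, bin_factor = 8, mask_radius = 0)
  expect_equal(as.vector(f8$features), rep(64, 4))
  # masking zeroes the central disc of every feature vector
  f2 <- preprocess_patterns(ones, bin_factor = 2, mask_radius = 2)
  B <- matrix(f2$features[1, ], 8, 8)
  ctr <- c(17 / 2, 17 / 2) / 2 + 0.5
  d2 <- (row(B) - ctr[1])^2 + (col(B) - ctr[2])^2
  expect_true(all(B[d2 <= 4] == 0))
  expect_true(all(B[d2 > 4] == 4))
  # binning conserves counts outside the mask
  expect_equal(sum(B), sum(d2 > 4) * 4)
})

test_that("K = 1 returns the global average pattern", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5)
  m <- kmeans_cluster(X, 1, seed = 1)
  expect_equal(as.vector(m$means), colMeans(X))
  expect_true(all(m$assignments == 1))
})

test_that("WCSS is non-increasing and matches the recomputed means", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 3), 20, 3))
  for (K in 2:4) {
    m <- kmeans_cluster(X, K, seed = K)
    expect_true(all(diff(m$wcss) <= 1e-9))
    for (k in seq_len(K)) {
      expect_equal(as.vector(m$means[k, ]),
                   colMeans(X[m$assignments == k, , drop = FALSE]))
    }
  }
})

test_that("k-means++ with restarts attains the exhaustive-partition optimum", {
  # brute-force oracle over all 2-partitions of <= 8 points
  brute_wcss <- function(X, K = 2) {
    n <- nrow(X)
    best <- Inf
    for (code in 0:(2^(n - 1) - 1)) {
      grp <- as.integer(intToBits(code))[1:n]
      if (length(unique(grp)) < K) next
      w <- 0
      for (g in unique(grp)) {
        S <- X[grp == g, , drop = FALSE]
        w <- w + sum(sweep(S, 2, colMeans(S))^2)
      }
      best <- min(best, w)
    }
    best
  }
  set.seed(11)
  for (rep in 1:4) {
    X <- matrix(rnorm(6 * 2, sd = 2), 6, 2)
    m <- kmeans_cluster(X, 2, seed = rep, nstart = 10)
    expect_equal(utils::tail(m$wcss, 1), brute_wcss(X), tolerance = 1e-8)
  }
})

test_that("k-means agrees with an independent implementation on WCSS", {
  set.seed(19)
  X <- rbind(matrix(rnorm(100, 0), 25, 4), matrix(rnorm(100, 4), 25, 4))
  ours <- utils::tail(kmeans_cluster(X, 2, seed = 3, nstart = 10)$wcss, 1)
  ref <- stats::kmeans(X, 2, nstart = 10)$tot.withinss
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("two synthetic tilt domains are recovered exactly at K = 2", {
  det <- small_detector()
  ph <- phantom_bands(4, 8, rbind(c(1, -1), c(-1, 1)), thickness = 200,
                      vacuum_cols = 0)
  scan <- generate_scan(ph, probe_model(), det, seed = 31)
  bg <- estimate_background(scan)
  sp <- sparsify_scan(scan, bg)
  ft <- preprocess_patterns(sp, bin_factor = 4, mask_radius = 3)
  m <- kmeans_cluster(ft, 2, seed = 2, nstart = 5)
  expect_equal(rand_index(m$assignments, as.vector(ph$domains)), 1)
})

test_that("pattern order does not change the partition", {
  set.seed(41)
  X <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 5), 10, 4))
  m1 <- kmeans_cluster(X, 2, seed = 9, nstart = 5)
  perm <- sample(nrow(X))
  m2 <- kmeans_cluster(X[perm, ], 2, seed = 9, nstart = 5)
  expect_equal(rand_index(m1$assignments[perm], m2$assignments), 1)
})

test_that("G-means keeps one Gaussian blob whole and splits two", {
  set.seed(13)
  one <- matrix(rnorm(200 * 2), 200, 2)
  g1 <- gmeans_select_K(one, seed = 2)
  expect_equal(g1$K, 1L)
  two <- rbind(matrix(rnorm(150 * 2, 0, 1), 150, 2),
               matrix(rnorm(150 * 2, 12, 1), 150, 2))
  g2 <- gmeans_select_K(two, seed = 2)
  expect_equal(g2$K, 2L)
  # independent check of the split decision: the projection of the mixed
  # data onto the two-centre axis fails Anderson-Darling at alpha = 0.001,
  # each pure blob passes
  km <- stats::kmeans(two, 2, nstart = 5)
  v <- km$centers[1, ] - km$centers[2, ]
  expect_lt(nortest::ad.test(as.vector(two %*% v))$p.value, 0.001)
  expect_gt(nortest::ad.test(as.vector(one %*% v))$p.value, 0.001)
})

test_that("near-empty vacuum features do not cause runaway splitting", {
  set.seed(17)
  # masked vacuum patterns: mostly zero with sparse stray counts
  # (heavily non-Gaussian), plus two genuine domains
  vac <- matrix(rpois(60 * 30, 0.05), 60, 30)
  d1 <- matrix(rpois(40 * 30, 4), 40, 30)
  d2 <- cbind(matrix(rpois(40 * 15, 12), 40, 15),
              matrix(rpois(40 * 15, 0.5), 40, 15))
  g <- gmeans_select_K(rbind(vac, d1, d2), seed = 3, max_K = 12)
  expect_lte(g$K, 12)
  expect_gte(g$K, 2)
})

test_that("spatial maps, cluster means and area arithmetic are exact", {
  shape <- c(4L, 4L)
  frames <- vector("list", 16)
  board <- outer(1:4, 1:4, function(a, b) (a + b) %% 2 + 1)
  for (ix in 1:4) for (iy in 1:4) {
    M <- matrix(0, 8, 8)
    M[2 + board[iy, ix], 3] <- 10
    frames[[iy + (ix - 1) * 4]] <- M
  }
  sc <- make_sparse_scan(frames, c(4, 4), step_nm = 20)
  model <- structure(list(K = 2L, assignments = as.vector(board),
                          means = NULL, wcss = 0, scan_shape = c(4L, 4L)),
                     class = "cluster_model")
  sm <- cluster_spatial_map(model, sc)
  expect_equal(sm$label_map, board)
  expect_equal(sm$sizes, c(8L, 8L))
  expect_equal(sm$areas_nm2, c(3200, 3200))
  # per-cluster means come from the unbinned frames
  expect_equal(sm$means[[1]][3, 3], 10)
  expect_equal(sm$means[[2]][4, 3], 10)
  # 400 positions at a 20 nm step -> 1.6e5 nm^2
  model2 <- structure(list(K = 1L, assignments = rep(1L, 400),
                           means = NULL, wcss = 0,
                           scan_shape = c(20L, 20L)), class = "cluster_model")
  frames400 <- rep(list(matrix(0, 4, 4)), 400)
  sc400 <- make_sparse_scan(frames400, c(20, 20), step_nm = 20)
  expect_equal(cluster_spatial_map(model2, sc400)$areas_nm2, 1.6e5)
})
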