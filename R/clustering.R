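# Unsupervised classification of diffraction patterns.
#
# Patterns are sum-binned (8-fold by default) for SNR, the central beam is
# masked out so transmission/thickness does not dominate, and the
# flattened frames are clustered by k-means (k-means++ seeding, Lloyd
# iterations on the plain Euclidean objective, stop at 100 iterations or
# WCSS stagnation). K is chosen by G-means: clusters whose 2-means
# projection fails an Anderson-Darling normality test at a = 0.001 are
# split, and splitting stops once at least 80% of clusters test Gaussian
# (near-empty vacuum clusters never look Gaussian, so the break is what
# makes the recursion converge).

#' Bin and mask patterns into feature vectors
#'
#' Sum-bins every frame by `bin_factor`, zeroes a disc of `mask_radius`
#' binned pixels around the (binned) beam centre, and flattens to a
#' feature matrix. Binning conserves total counts; remainder rows/columns
#' beyond the last full bin are dropped.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param bin_factor integer binning factor (>= 1).
#' @param mask_radius radius of the central mask in binned pixels
#'   (0 = no mask).
#' @return object of class `pattern_features`: list with `features`
#'   (n_patterns x d matrix, row-major scan order), `binned_dim`,
#'   `bin_factor`, `mask_radius`, `scan_shape`.
#' @export
preprocess_patterns <- function(scan, bin_factor = 8, mask_radius = 3) {
  stopifnot(bin_factor >= 1)
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  nby <- fs[1] %/% bin_factor; nbx <- fs[2] %/% bin_factor
  gy <- rep(seq_len(nby), each = bin_factor)
  gx <- rep(seq_len(nbx), each = bin_factor)
  ctr_b <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2) / bin_factor + 0.5
  mask <- if (mask_radius > 0) {
    outer(seq_len(nby) - ctr_b[1], seq_len(nbx) - ctr_b[2],
          function(a, b) a^2 + b^2) <= mask_radius^2
  } else matrix(FALSE, nby, nbx)
  if (all(mask)) stop("mask radius larger than the binned frame")
  X <- matrix(0, prod(sh), nby * nbx)
  for (ix in seq_len(sh[2])) for (iy in seq_len(sh[1])) {
    M <- .frame_dense(scan, iy, ix)[seq_along(gy), seq_along(gx)]
    B <- t(rowsum(t(rowsum(M, gy)), gx))
    B[mask] <- 0
    X[iy + (ix - 1L) * sh[1], ] <- as.vector(B)
  }
  structure(list(features = X, binned_dim = c(nby, nbx),
                 bin_factor = bin_factor, mask_radius = mask_radius,
                 scan_shape = sh),
            class = "pattern_features")
}

# squared Euclidean distances of all rows of X to one centre
.d2_to <- function(X, centre) rowSums(sweep(X, 2, centre)^2)

# k-means++ seeding (D^2 sampling); RNG state of the caller is used
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centres <- matrix(0, K, ncol(X))
  centres[1, ] <- X[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- .d2_to(X, centres[1, ])
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centres[k, ] <- X[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, .d2_to(X, centres[k, ]))
    }
  }
  centres
}

# Lloyd iterations; returns assignments, centres and the per-iteration WCSS
lloyd <- function(X, centres, max_iter = 100, tol = 1e-6) {
  K <- nrow(centres)
  wcss <- numeric(0)
  assign <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    D <- vapply(seq_len(K), function(k) .d2_to(X, centres[k, ]),
                numeric(nrow(X)))
    D <- matrix(D, nrow(X))
    assign_new <- max.col(-D, ties.method = "first")
    # empty cluster: re-seed at the pattern farthest from its current
    # centre (never stealing a cluster's last member)
    for (k in seq_len(K)) {
      if (!any(assign_new == k)) {
        sizes <- tabulate(assign_new, K)
        cand <- which(sizes[assign_new] > 1L)
        if (!length(cand)) next
        far <- cand[which.max(D[cbind(cand, assign_new[cand])])]
        centres[k, ] <- X[far, ]
        assign_new[far] <- k
      }
    }
    for (k in seq_len(K)) {
      if (any(assign_new == k))
        centres[k, ] <- colMeans(X[assign_new == k, , drop = FALSE])
    }
    w <- sum(vapply(seq_len(K), function(k) {
      sum(.d2_to(X[assign_new == k, , drop = FALSE], centres[k, ]))
    }, numeric(1)))
    assign <- assign_new
    wcss <- c(wcss, w)
    if (it > 1 && (wcss[it - 1] - w) <= tol * max(wcss[it - 1], 1))
      break
  }
  list(assignments = assign, centres = centres, wcss = wcss)
}

#' k-means clustering of pattern features
#'
#' k-means++ initialisation followed by Lloyd iterations minimising the
#' within-cluster sum of squared Euclidean distances; stops after
#' `max_iter` iterations or when the WCSS stagnates. Deterministic for a
#' given seed. With `nstart > 1`, the restart with the lowest final WCSS
#' wins.
#'
#' @param features a [preprocess_patterns()] result or a numeric matrix
#'   (rows = patterns).
#' @param K number of clusters (1 <= K <= n patterns).
#' @param seed integer seed.
#' @param max_iter iteration cap (100, matching the pipeline default).
#' @param tol relative WCSS change defining "stagnated".
#' @param nstart number of k-means++ restarts.
#' @return object of class `cluster_model`: `K`, `assignments`, `means`
#'   (K x d centre matrix), `wcss` (per-iteration trace of the winning
#'   run), `scan_shape` (if known).
#' @export
kmeans_cluster <- function(features, K, seed = 1, max_iter = 100,
                           tol = 1e-6, nstart = 1) {
  X <- if (inherits(features, "pattern_features")) features$features else features
  stopifnot(K >= 1, K <= nrow(X))
  best <- NULL
  for (s in seq_len(nstart)) {
    set.seed(as.integer(seed) + s - 1L)
    fit <- lloyd(X, kmeanspp_init(X, K), max_iter, tol)
    if (is.null(best) || utils::tail(fit$wcss, 1) < utils::tail(best$wcss, 1))
      best <- fit
  }
  structure(list(K = K, assignments = best$assignments,
                 means = best$centres, wcss = best$wcss,
                 scan_shape = if (inherits(features, "pattern_features"))
                   features$scan_shape else NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster model: K=%d, %d patterns, final WCSS %.4g (%d iterations)\n",
              x$K, length(x$assignments), utils::tail(x$wcss, 1),
              length(x$wcss)))
  invisible(x)
}

# Anderson-Darling p-value (case 3: mean and variance estimated) of the
# projection of a cluster onto its 2-means centroid axis; degenerate
# projections count as Gaussian (they cannot justify a split)
.ad_p_projection <- function(X, seed) {
  if (nrow(X) < 8) return(1)
  set.seed(as.integer(seed))
  fit <- lloyd(X, kmeanspp_init(X, 2), max_iter = 50)
  v <- fit$centres[1, ] - fit$centres[2, ]
  nv <- sum(v^2)
  if (nv == 0) return(1)
  proj <- as.vector(X %*% v) / sqrt(nv)
  if (stats::sd(proj) < 1e-12) return(1)
  p <- try(nortest::ad.test(proj)$p.value, silent = TRUE)
  if (inherits(p, "try-error") || !is.finite(p)) 1 else p
}

#' Select the number of clusters by G-means
#'
#' Recursive 2-means splitting: a cluster is split when the projection of
#' its members onto the axis joining its two children's centres fails the
#' Anderson-Darling normality test at level `alpha`. Splitting stops when
#' at least `gaussian_fraction` of the current clusters test Gaussian (or
#' `max_K` is reached); the final K is then refined by a full k-means run.
#'
#' @param features a [preprocess_patterns()] result or feature matrix.
#' @param alpha significance level for the Anderson-Darling test (0.001,
#'   the pipeline default).
#' @param gaussian_fraction stop once this fraction of clusters is
#'   Gaussian (0.8).
#' @param seed integer seed.
#' @param max_K hard cap on K.
#' @param min_size clusters smaller than this are never split.
#' @return list with `K`, `model` (a refined [kmeans_cluster()] fit) and
#'   `gaussian` (logical per final pre-refinement cluster).
#' @export
gmeans_select_K <- function(features, alpha = 0.001, gaussian_fraction = 0.8,
                            seed = 1, max_K = 50, min_size = 8) {
  X <- if (inherits(features, "pattern_features")) features$features else features
  if (nrow(X) < 2) stop("need at least 2 patterns")
  assign <- rep(1L, nrow(X))
  gaussian <- c(FALSE)
  next_seed <- as.integer(seed)
  repeat {
    K <- length(gaussian)
    if (mean(gaussian) >= gaussian_fraction || K >= max_K) break
    k <- which(!gaussian)[1]
    members <- which(assign == k)
    if (length(members) < max(min_size, 2)) { gaussian[k] <- TRUE; next }
    next_seed <- next_seed + 1L
    p <- .ad_p_projection(X[members, , drop = FALSE], next_seed)
    if (p >= alpha) { gaussian[k] <- TRUE; next }
    set.seed(next_seed)
    fit <- lloyd(X[members, , drop = FALSE], kmeanspp_init(X[members, , drop = FALSE], 2),
                 max_iter = 50)
    if (length(unique(fit$assignments)) < 2) { gaussian[k] <- TRUE; next }
    assign[members[fit$assignments == 2]] <- K + 1L
    gaussian[k] <- FALSE
    gaussian <- c(gaussian, FALSE)
  }
  K <- length(gaussian)
  model <- kmeans_cluster(features, K, seed = as.integer(seed), nstart = 3)
  list(K = K, model = model, gaussian = gaussian)
}

#' Spatial cluster map and per-cluster average patterns
#'
#' Lays the cluster assignments back onto the scan grid and computes each
#' cluster's average pattern from the unbinned, unmasked frames (the
#' input to orientation indexing), plus cluster areas from the step size.
#'
#' @param model a [kmeans_cluster()] fit.
#' @param scan the `scan4d` or `sparse_scan` the features came from.
#' @param step_nm scan step size in nm (default from scan metadata).
#' @return list with `label_map` (integer matrix on the scan grid),
#'   `means` (list of K dense average patterns), `sizes` (positions per
#'   cluster), `areas_nm2`.
#' @export
cluster_spatial_map <- function(model, scan, step_nm = NULL) {
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  stopifnot(length(model$assignments) == prod(sh))
  if (is.null(step_nm)) step_nm <- scan$meta$step_nm
  label_map <- matrix(model$assignments, sh[1], sh[2])
  means <- vector("list", model$K)
  sizes <- integer(model$K)
  for (k in seq_len(model$K)) {
    acc <- matrix(0, fs[1], fs[2])
    members <- which(label_map == k, arr.ind = TRUE)
    sizes[k] <- nrow(members)
    for (i in seq_len(nrow(members)))
      acc <- acc + .frame_dense(scan, members[i, 1], members[i, 2])
    means[[k]] <- acc / max(sizes[k], 1L)
  }
  list(label_map = label_map, means = means, sizes = sizes,
       areas_nm2 = sizes * step_nm^2)
}
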