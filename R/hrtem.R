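# Real-space counterpart analysis for HRTEM lattice images: tile the
# image into non-overlapping 128 x 128 sub-images, pick K by the elbow
# method (more stable than Anderson-Darling on noisy image data), cluster
# tiles with a small integer shift search absorbing lattice misalignment
# between tiles, and Fourier-filter the class averages.

#' Tile an image into non-overlapping squares
#'
#' Row-major, non-overlapping `tile_size` tiles; remainder margins beyond
#' the last full tile are dropped.
#'
#' @param image numeric matrix.
#' @param tile_size tile edge in pixels (128 by protocol).
#' @return object of class `tile_set`: list with `tiles` (list of
#'   matrices), `grid` (tiles_y, tiles_x), `tile_size`, `source_dim`.
#' @export
tile_image <- function(image, tile_size = 128) {
  stopifnot(is.matrix(image))
  ny <- nrow(image) %/% tile_size
  nx <- ncol(image) %/% tile_size
  if (ny < 1 || nx < 1) stop("image smaller than one tile")
  tiles <- vector("list", ny * nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    tiles[[(i - 1L) * nx + j]] <-
      image[(i - 1L) * tile_size + seq_len(tile_size),
            (j - 1L) * tile_size + seq_len(tile_size)]
  }
  structure(list(tiles = tiles, grid = c(ny, nx), tile_size = tile_size,
                 source_dim = dim(image)),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile set: %d x %d tiles of %d px from a %d x %d image\n",
              x$grid[1], x$grid[2], x$tile_size,
              x$source_dim[1], x$source_dim[2]))
  invisible(x)
}

.tile_matrix <- function(tiles) {
  if (inherits(tiles, "tile_set"))
    t(vapply(tiles$tiles, as.vector, numeric(length(tiles$tiles[[1]]))))
  else tiles
}

#' Choose K by the elbow method
#'
#' Runs k-means for k = 1..k_max under fixed seeds and returns the k with
#' the largest discrete second difference of the WCSS curve — the elbow.
#' A monotone-flat curve yields K = 1 with a warning.
#'
#' @param tiles a [tile_image()] set or feature matrix.
#' @param k_max largest K to consider (>= 2).
#' @param seed integer seed.
#' @param nstart k-means++ restarts per k.
#' @return chosen K, with attribute `"wcss"` (the curve).
#' @export
elbow_K <- function(tiles, k_max = 8, seed = 1, nstart = 3) {
  stopifnot(k_max >= 2)
  X <- .tile_matrix(tiles)
  k_max <- min(k_max, nrow(X))
  wcss <- vapply(seq_len(k_max), function(k)
    utils::tail(kmeans_cluster(X, k, seed = seed, nstart = nstart)$wcss, 1),
    numeric(1))
  if (k_max < 3 || max(wcss) - min(wcss) <= 1e-12 * max(wcss, 1)) {
    warning("WCSS curve is flat; returning K = 1")
    return(structure(1L, wcss = wcss))
  }
  d2 <- wcss[1:(k_max - 2)] - 2 * wcss[2:(k_max - 1)] + wcss[3:k_max]
  structure(which.max(d2) + 1L, wcss = wcss)
}

# minimum mean-squared difference between a tile and a centre over all
# integer shifts in a w x w window; comparison on the overlap region only,
# normalised by overlap area. Returns the distance and the best shift.
.shift_dist <- function(tile, centre_m, w) {
  m <- (w - 1L) %/% 2L
  best <- Inf; bs <- c(0L, 0L)
  n <- nrow(tile)
  for (sy in -m:m) for (sx in -m:m) {
    ys <- max(1, 1 + sy):min(n, n + sy)
    xs <- max(1, 1 + sx):min(n, n + sx)
    d <- tile[ys - sy, xs - sx] - centre_m[ys, xs]
    msd <- sum(d * d) / length(d)
    if (msd < best) { best <- msd; bs <- c(sy, sx) }
  }
  list(msd = best, shift = bs)
}

#' Cluster tiles with a pixel-wise shift search
#'
#' k-means over tiles where the tile-to-centre distance is minimised over
#' all integer translations in a `shift_search` x `shift_search` window
#' (valid-region comparison normalised by overlap area); each tile is
#' shifted by its best offset before entering its cluster's average. A
#' 1 x 1 window reduces to plain k-means.
#'
#' @param tiles a [tile_image()] set or feature matrix of flattened
#'   square tiles.
#' @param K number of clusters.
#' @param shift_search odd window size (5 by protocol).
#' @param seed integer seed.
#' @param max_iter iteration cap.
#' @return object of class `tile_cluster_model`: `K`, `assignments`,
#'   `shifts` (n x 2 best offsets), `means` (list of centre matrices),
#'   `objective` (per-iteration mean of min shift-distances).
#' @export
cluster_tiles <- function(tiles, K, shift_search = 5, seed = 1,
                          max_iter = 30) {
  stopifnot(shift_search %% 2 == 1)
  X <- .tile_matrix(tiles)
  n <- nrow(X)
  side <- as.integer(sqrt(ncol(X)))
  stopifnot(side * side == ncol(X))
  as_m <- function(v) matrix(v, side, side)
  set.seed(as.integer(seed))
  centres <- lapply(sample.int(n, K), function(i) as_m(X[i, ]))
  assign <- integer(n); shifts <- matrix(0L, n, 2)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    obj <- 0
    for (i in seq_len(n)) {
      tile <- as_m(X[i, ])
      best <- Inf; bk <- 1L; bshift <- c(0L, 0L)
      for (k in seq_len(K)) {
        r <- .shift_dist(tile, centres[[k]], shift_search)
        if (r$msd < best) { best <- r$msd; bk <- k; bshift <- r$shift }
      }
      assign[i] <- bk; shifts[i, ] <- bshift
      obj <- obj + best
    }
    objective <- c(objective, obj / n)
    new_centres <- vector("list", K)
    for (k in seq_len(K)) {
      members <- which(assign == k)
      if (!length(members)) { new_centres[[k]] <- centres[[k]]; next }
      acc <- matrix(0, side, side); wgt <- matrix(0, side, side)
      for (i in members) {
        sh <- shifts[i, ]
        ys <- max(1, 1 + sh[1]):min(side, side + sh[1])
        xs <- max(1, 1 + sh[2]):min(side, side + sh[2])
        acc[ys, xs] <- acc[ys, xs] + as_m(X[i, ])[ys - sh[1], xs - sh[2]]
        wgt[ys, xs] <- wgt[ys, xs] + 1
      }
      new_centres[[k]] <- ifelse(wgt > 0, acc / pmax(wgt, 1), centres[[k]])
    }
    converged <- it > 1 &&
      abs(objective[it - 1] - objective[it]) <= 1e-9 * max(objective[it - 1], 1)
    centres <- new_centres
    if (converged) break
  }
  structure(list(K = K, assignments = assign, shifts = shifts,
                 means = centres, objective = objective),
            class = "tile_cluster_model")
}

#' Fourier-filter a class average
#'
#' Zeroes every Fourier coefficient whose magnitude is below the mean plus
#' 2 SD of all magnitudes (DC term excluded from the statistics and always
#' retained) and inverse-transforms, keeping only the periodic lattice
#' signal.
#'
#' @param image real-valued matrix.
#' @param n_sd threshold level in standard deviations above the mean
#'   magnitude (2 by protocol).
#' @return filtered real image, same dimensions.
#' @export
fourier_filter <- function(image, n_sd = 2) {
  stopifnot(is.matrix(image))
  Fz <- stats::fft(image)
  mag <- Mod(Fz)
  m <- mag[-1]                       # exclude the DC term
  thr <- mean(m) + n_sd * stats::sd(m)
  keep <- mag >= thr
  keep[1, 1] <- TRUE
  Re(stats::fft(Fz * keep, inverse = TRUE)) / length(Fz)
}
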