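# Shared fixtures: a desk-scale detector small enough for property loops,
# hand-built sparse patterns/backgrounds, and a partition-agreement score.

small_detector <- function(...) {
  detector_model(n_ky = 64L, n_kx = 64L, strip_width = 16L,
                 px_per_invA = 42, beam_radius_px = 3, ...)
}

# background model with a known threshold (for floor-identity tests)
make_bg <- function(threshold, n_kx, strip_width = n_kx,
                    strip_offsets = 0) {
  n_strips <- ceiling(n_kx / strip_width)
  structure(list(strip_offsets = rep_len(strip_offsets, n_strips),
                 strip_width = as.integer(strip_width),
                 gauss_mu = 0, gauss_sigma = threshold / 5,
                 threshold = threshold, threshold_mode = "mu_plus_5sd"),
            class = "background_model")
}

# sparse pattern from an entry matrix (k_y, k_x, count)
make_pattern <- function(entries, shape) {
  entries <- entries[order(entries[, 1], entries[, 2]), , drop = FALSE]
  colnames(entries) <- c("k_y", "k_x", "count")
  structure(entries, frame_shape = shape, class = "sparse_pattern")
}

# sparse scan from a scan_y x scan_x list-matrix of dense frames
make_sparse_scan <- function(frames_dense, shape, step_nm = 20) {
  frame_shape <- dim(frames_dense[[1]])
  frames <- lapply(frames_dense, function(M) {
    nz <- which(M != 0, arr.ind = TRUE)
    make_pattern(cbind(nz, M[nz]), frame_shape)
  })
  totals <- matrix(vapply(frames, function(p) sum(p[, 3]), numeric(1)),
                   shape[1], shape[2])
  structure(list(frames = frames, shape = shape, frame_shape = frame_shape,
                 totals = totals, background = NULL,
                 meta = list(step_nm = step_nm), truth = NULL),
            class = "sparse_scan")
}

# Rand index between two partitions (1 = identical up to relabelling)
rand_index <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(sa == sb)
}

# counted cluster-average pattern of a whole single-tilt synthetic scan
counted_average <- function(tilt, thickness, detector, probe, seed,
                            n_y = 4, n_x = 6) {
  ph <- phantom_bands(n_y, n_x, rbind(tilt), thickness = thickness,
                      vacuum_cols = 0)
  scan <- generate_scan(ph, probe, detector, seed = seed)
  bg <- estimate_background(scan)
  sp <- sparsify_scan(scan, bg)
  acc <- matrix(0, detector$n_ky, detector$n_kx)
  for (ix in seq_len(n_x)) for (iy in seq_len(n_y))
    acc <- acc + densify_pattern(sp$frames[[iy + (ix - 1) * n_y]])
  acc / (n_y * n_x)
}
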