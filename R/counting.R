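# Hybrid electron counting.
#
# Raw analog frames are reduced to sparse integer electron counts in three
# steps shared across a whole scan: (i) per-strip dark-current medians,
# (ii) a Gaussian fitted to the pooled background pixel distribution whose
# mu + 5 sigma defines the counting threshold, (iii) floor division of
# every offset-subtracted pixel by the threshold, which recovers part of
# the dynamic range lost to coincident electrons at the bright central
# beam. Zero counts are dropped and frames become coordinate lists.

#' Estimate the scan-wide background model
#'
#' Computes per-strip dark-current offsets as the median of each vertical
#' pixel strip over all frames, then fits a Gaussian to the histogram of
#' pooled offset-subtracted pixel values (values above the trim quantile —
#' the sparse electron-event tail — are excluded from the fit). The
#' counting threshold is `mu + 5 * sigma` of that fit.
#'
#' @param scan a `scan4d` (raw analog frames).
#' @param strip_width strip width in columns; defaults to the detector's.
#' @param trim_quantile upper quantile above which pixel values are
#'   excluded from the background fit.
#' @param n_bins number of histogram bins for the least-squares fit.
#' @param threshold_mode `"mu_plus_5sd"` (default) or `"5sd"` (5 sigma
#'   about zero, assuming perfect dark subtraction).
#' @return object of class `background_model` with `strip_offsets`,
#'   `gauss_mu`, `gauss_sigma`, `threshold`, `strip_width`.
#' @export
estimate_background <- function(scan, strip_width = NULL,
                                trim_quantile = 0.995, n_bins = 200,
                                threshold_mode = c("mu_plus_5sd", "5sd")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(scan, "scan4d"))
  d <- dim(scan$data)
  if (is.null(strip_width)) strip_width <- scan$meta$detector$strip_width
  n_kx <- d[4]
  strip_id <- ((seq_len(n_kx) - 1L) %/% strip_width) + 1L
  n_strips <- max(strip_id)

  strip_offsets <- numeric(n_strips)
  for (s in seq_len(n_strips)) {
    v <- as.vector(scan$data[, , , strip_id == s])
    if (max(v) == min(v))
      stop(sprintf("degenerate fit: strip %d has zero variance", s))
    strip_offsets[s] <- stats::median(v)
  }

  sub <- sweep(matrix(aperm(scan$data, c(3, 4, 1, 2)),
                      nrow = d[3] * d[4]),
               1, rep(strip_offsets[strip_id], each = d[3]), "-")
  v <- as.vector(sub)
  v <- v[v <= stats::quantile(v, trim_quantile)]
  if (stats::sd(v) == 0) stop("degenerate fit: zero-variance background")

  # bin over a robust window about the background mode so sparse electron
  # events (far in the upper tail) cannot stretch the histogram range
  med <- stats::median(v)
  s0 <- stats::mad(v)
  if (s0 == 0) stop("degenerate fit: zero-spread background")
  vw <- v[v >= med - 10 * s0 & v <= med + 10 * s0]
  h <- graphics::hist(vw, breaks = n_bins, plot = FALSE)
  fit <- fit_gaussian_histogram(h$mids, h$counts, mu0 = med, sigma0 = s0)
  mu <- fit["mu"]; sigma <- fit["sigma"]
  threshold <- if (threshold_mode == "mu_plus_5sd") mu + 5 * sigma else 5 * sigma
  structure(list(strip_offsets = strip_offsets,
                 strip_width = as.integer(strip_width),
                 gauss_mu = unname(mu), gauss_sigma = unname(sigma),
                 threshold = unname(threshold),
                 threshold_mode = threshold_mode),
            class = "background_model")
}

# least-squares Gaussian fit to histogram counts; falls back to the moment
# estimates if the optimiser fails to improve on them
fit_gaussian_histogram <- function(mids, counts, mu0, sigma0) {
  obj <- function(p) {
    if (p[3] <= 0) return(Inf)
    sum((counts - p[1] * exp(-(mids - p[2])^2 / (2 * p[3]^2)))^2)
  }
  p0 <- c(A = max(counts), mu = mu0, sigma = max(sigma0, 1e-6))
  res <- try(stats::optim(p0, obj), silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$value) ||
      res$par[3] <= 0)
    stop("Gaussian background fit did not converge")
  c(mu = unname(res$par[2]), sigma = unname(res$par[3]))
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background: %d strips, gaussian mu=%.3f sigma=%.3f, threshold=%.3f (%s)\n",
              length(x$strip_offsets), x$gauss_mu, x$gauss_sigma,
              x$threshold, x$threshold_mode))
  invisible(x)
}

#' Hybrid-count a single frame
#'
#' Subtracts the strip offsets and assigns every pixel
#' `floor(value / threshold)` electron counts; zero counts are dropped and
#' the frame becomes a sorted coordinate list. Floor division (rather than
#' a binary threshold) lets pixels struck by coincident electrons report
#' multiple counts.
#'
#' @param frame numeric matrix of raw analog counts.
#' @param bg a [estimate_background()] model.
#' @return object of class `sparse_pattern`: integer matrix with columns
#'   `k_y`, `k_x`, `count`, sorted by (k_y, k_x), with attribute
#'   `frame_shape`.
#' @export
hybrid_count <- function(frame, bg) {
  stopifnot(is.matrix(frame), inherits(bg, "background_model"))
  strip_id <- ((seq_len(ncol(frame)) - 1L) %/% bg$strip_width) + 1L
  if (max(strip_id) != length(bg$strip_offsets))
    stop("frame dimensions do not match the background strip layout")
  v <- sweep(frame, 2, bg$strip_offsets[strip_id], "-")
  counts <- floor(pmax(v, 0) / bg$threshold)
  nz <- which(counts >= 1, arr.ind = TRUE)
  out <- cbind(k_y = nz[, 1], k_x = nz[, 2],
               count = as.integer(counts[nz]))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  structure(out, frame_shape = dim(frame), class = "sparse_pattern")
}

#' Densify a sparse pattern
#' @param pattern a `sparse_pattern`.
#' @return integer matrix of counts with the original frame shape.
#' @export
densify_pattern <- function(pattern) {
  shape <- attr(pattern, "frame_shape")
  M <- matrix(0L, shape[1], shape[2])
  if (nrow(pattern)) M[pattern[, 1:2, drop = FALSE]] <- pattern[, 3]
  M
}

#' Hybrid-count a whole scan
#'
#' Applies [hybrid_count()] with one shared background model to every
#' frame, yielding a `sparse_scan`: a row-major list of coordinate-list
#' patterns plus per-frame totals. This is the ~hundreds-fold data
#' reduction step of the pipeline.
#'
#' @param scan a `scan4d`.
#' @param bg a [estimate_background()] model (estimated from this scan).
#' @return object of class `sparse_scan` with `frames` (list of
#'   `sparse_pattern`), `shape` (scan grid), `frame_shape`, `totals`
#'   (per-position recovered electron counts), `meta`, `truth`.
#' @export
sparsify_scan <- function(scan, bg) {
  stopifnot(inherits(scan, "scan4d"))
  d <- dim(scan$data)
  frames <- vector("list", d[1] * d[2])
  totals <- matrix(0, d[1], d[2])
  for (ix in seq_len(d[2])) for (iy in seq_len(d[1])) {
    sp <- hybrid_count(scan$data[iy, ix, , ], bg)
    frames[[iy + (ix - 1L) * d[1]]] <- sp
    totals[iy, ix] <- sum(sp[, 3])
  }
  structure(list(frames = frames, shape = d[1:2], frame_shape = d[3:4],
                 totals = totals, background = bg,
                 meta = scan$meta, truth = scan$truth),
            class = "sparse_scan")
}

#' @export
print.sparse_scan <- function(x, ...) {
  cat(sprintf("sparse 4DSTEM scan: %d x %d positions, %d x %d detector, mean %.0f counts/frame\n",
              x$shape[1], x$shape[2], x$frame_shape[1], x$frame_shape[2],
              mean(x$totals)))
  invisible(x)
}

#' @export
dim.sparse_scan <- function(x) c(x$shape, x$frame_shape)

# fetch frame (iy, ix) of a sparse scan
sparse_frame <- function(sp, iy, ix) sp$frames[[iy + (ix - 1L) * sp$shape[1]]]

#' Densify a sparse scan
#' @param sp a `sparse_scan`.
#' @return 4-D integer array (scan_y, scan_x, k_y, k_x).
#' @export
densify_scan <- function(sp) {
  out <- array(0L, c(sp$shape, sp$frame_shape))
  for (ix in seq_len(sp$shape[2])) for (iy in seq_len(sp$shape[1]))
    out[iy, ix, , ] <- densify_pattern(sparse_frame(sp, iy, ix))
  out
}

#' Dose estimate for a scan step
#'
#' Electrons per scan step and fluence from the probe parameters:
#' `electrons = rate * dwell`, `fluence = electrons / (FWHM in Å)^2`.
#' At the experimental operating point (1.5e6 e-/s, 2.5 ms, 6 nm probe)
#' this gives 3750 electrons and ~1 e-/Å² per step.
#'
#' @param probe a [probe_model()].
#' @return object of class `dose_estimate` with `electrons_per_step`,
#'   `probe_area_A2`, `fluence` (e-/Å²), `pattern_rate_hz`.
#' @export
estimate_dose <- function(probe) {
  stopifnot(inherits(probe, "probe_model"))
  electrons <- probe$electron_rate * probe$dwell_s
  area <- (probe$fwhm_nm * 10)^2
  structure(list(electrons_per_step = electrons,
                 probe_area_A2 = area,
                 fluence = if (area > 0) electrons / area else 0,
                 pattern_rate_hz = if (probe$dwell_s > 0) 1 / probe$dwell_s else Inf),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("dose: %.0f e-/step over %.0f A^2 -> %.2f e-/A^2 (%.0f patterns/s)\n",
              x$electrons_per_step, x$probe_area_A2, x$fluence,
              x$pattern_rate_hz))
  invisible(x)
}
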