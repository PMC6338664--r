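# Crystal-thickness mapping.
#
# Thickness per scan position from the log-ratio formula used in EELS:
#   Z_xy = -lambda * ln(I_xy / I0)
# where I_xy is the integrated transmitted beam plus the integrated
# intensity at all Bragg peak positions, lambda the inelastic mean free
# path (332 nm for these peptide crystals), and I0 the vacuum reference
# taken as mean(vacuum integrals) - 2 * SD.

#' Integrated transmitted + Bragg intensity of one pattern
#'
#' Sums the counts inside the central disc and inside a disc around every
#' Bragg position. Bragg discs that overlap the central disc are excluded
#' (no double counting); where two Bragg discs overlap, each pixel is
#' credited to the nearer peak (which leaves the total unchanged).
#'
#' @param pattern a `sparse_pattern` or dense matrix.
#' @param beam_centre (row, col) of the central beam.
#' @param beam_radius central-disc integration radius, pixels.
#' @param bragg_positions optional n x 2 matrix of peak (row, col).
#' @param bragg_radius per-peak integration radius, pixels.
#' @return total intensity I_xy (0 for an empty pattern).
#' @export
integrate_transmission <- function(pattern, beam_centre, beam_radius,
                                   bragg_positions = NULL, bragg_radius = 4) {
  if (is.matrix(pattern) && !inherits(pattern, "sparse_pattern")) {
    nz <- which(pattern != 0, arr.ind = TRUE)
    entries <- cbind(nz, pattern[nz])
  } else {
    entries <- unclass(pattern)
  }
  if (is.null(entries) || nrow(entries) == 0L) return(0)
  d2c <- (entries[, 1] - beam_centre[1])^2 + (entries[, 2] - beam_centre[2])^2
  central <- d2c <= beam_radius^2
  total <- sum(entries[central, 3])
  if (!is.null(bragg_positions) && nrow(bragg_positions) > 0L) {
    pc <- sqrt((bragg_positions[, 1] - beam_centre[1])^2 +
                 (bragg_positions[, 2] - beam_centre[2])^2)
    keep <- pc > beam_radius + bragg_radius   # overlapping discs excluded
    bp <- bragg_positions[keep, , drop = FALSE]
    if (nrow(bp) > 0L && any(!central)) {
      rest <- entries[!central, , drop = FALSE]
      d2 <- outer(rest[, 1], bp[, 1], "-")^2 + outer(rest[, 2], bp[, 2], "-")^2
      total <- total + sum(rest[apply(d2, 1, min) <= bragg_radius^2, 3])
    }
  }
  total
}

#' Find Bragg peak positions in the scan-average pattern
#'
#' Local maxima of the mean pattern that exceed the azimuthal (radial-bin)
#' background by `n_sigma` standard deviations, outside the central disc.
#' Used when no peak set from the indexing stage is available.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param beam_radius central-disc radius, pixels.
#' @param n_sigma detection level above the azimuthal background.
#' @param bin_px radial bin width, pixels.
#' @return n x 2 matrix of peak (row, col) positions.
#' @export
find_bragg_peaks <- function(scan, beam_radius, n_sigma = 5, bin_px = 2) {
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  acc <- matrix(0, fs[1], fs[2])
  for (ix in seq_len(sh[2])) for (iy in seq_len(sh[1]))
    acc <- acc + .frame_dense(scan, iy, ix)
  acc <- acc / prod(sh)
  centre <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2)
  r <- sqrt((row(acc) - centre[1])^2 + (col(acc) - centre[2])^2)
  bin <- floor(r / bin_px)
  mu <- stats::ave(as.vector(acc), as.vector(bin), FUN = mean)
  sdv <- stats::ave(as.vector(acc), as.vector(bin),
                    FUN = function(v) stats::sd(v))
  sdv[is.na(sdv) | sdv == 0] <- Inf
  above <- matrix(as.vector(acc) > mu + n_sigma * sdv, nrow(acc))
  # 3x3 local maximum
  localmax <- acc >= translate_dense(acc, 1, 0) &
    acc >= translate_dense(acc, -1, 0) &
    acc >= translate_dense(acc, 0, 1) &
    acc >= translate_dense(acc, 0, -1) &
    acc >= translate_dense(acc, 1, 1) &
    acc >= translate_dense(acc, 1, -1) &
    acc >= translate_dense(acc, -1, 1) &
    acc >= translate_dense(acc, -1, -1)
  hits <- which(above & localmax & r > 1.5 * beam_radius, arr.ind = TRUE)
  colnames(hits) <- c("k_y", "k_x")
  hits
}

#' Vacuum reference intensity
#'
#' I0 = mean of the integrated central beam over vacuum positions minus
#' two population standard deviations, compensating fluctuations of the
#' central-beam intensity.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param vacuum_mask logical matrix on the scan grid selecting vacuum
#'   positions (>= 2 required).
#' @param beam_radius central-disc radius, pixels.
#' @param sd_correction set FALSE to use the plain mean.
#' @return I0 (counts), with attribute `"vacuum_integrals"`.
#' @export
estimate_I0 <- function(scan, vacuum_mask, beam_radius, sd_correction = TRUE) {
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  stopifnot(all(dim(vacuum_mask) == sh))
  pos <- which(vacuum_mask, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 vacuum positions")
  centre <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2)
  vals <- apply(pos, 1, function(p)
    integrate_transmission(.frame_dense(scan, p[1], p[2]), centre, beam_radius))
  sd_pop <- sqrt(mean((vals - mean(vals))^2))
  I0 <- mean(vals) - if (sd_correction) 2 * sd_pop else 0
  if (I0 <= 0) stop("I0 <= 0; vacuum region too noisy, supply I0 manually")
  structure(I0, vacuum_integrals = vals)
}

#' Log-ratio thickness map
#'
#' Applies Z = -lambda * ln(I/I0) at every scan position. Positions with
#' I >= I0 are clipped to 0; empty positions (I = 0) are set to an opaque
#' sentinel (Inf) and flagged.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param lambda_mfp mean free path in nm (332 nm for these crystals).
#' @param I0 vacuum reference from [estimate_I0()].
#' @param beam_radius central-disc radius, pixels.
#' @param bragg_positions optional peak set for the Bragg term (from
#'   [find_bragg_peaks()] or the indexing stage).
#' @param bragg_radius Bragg integration radius, pixels.
#' @param vacuum_mask optional logical matrix recorded with the result.
#' @return object of class `thickness_map` with `Z` (nm), `I`, `I0`,
#'   `lambda_mfp`, `opaque` (logical), `vacuum_mask`.
#' @export
thickness_map <- function(scan, lambda_mfp = 332, I0, beam_radius,
                          bragg_positions = NULL, bragg_radius = 4,
                          vacuum_mask = NULL) {
  stopifnot(lambda_mfp > 0, I0 > 0)
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  centre <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2)
  I <- matrix(0, sh[1], sh[2])
  for (ix in seq_len(sh[2])) for (iy in seq_len(sh[1]))
    I[iy, ix] <- integrate_transmission(.frame_dense(scan, iy, ix), centre,
                                        beam_radius, bragg_positions,
                                        bragg_radius)
  Z <- matrix(Inf, sh[1], sh[2])
  pos <- I > 0
  Z[pos] <- -lambda_mfp * log(I[pos] / I0)
  Z[I >= I0] <- 0
  structure(list(Z = Z, I = I, I0 = as.numeric(I0),
                 lambda_mfp = lambda_mfp, opaque = !pos,
                 vacuum_mask = vacuum_mask),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  fin <- is.finite(x$Z)
  cat(sprintf("thickness map: %d x %d, lambda=%.0f nm, I0=%.1f, Z in [%.0f, %.0f] nm (%d opaque)\n",
              nrow(x$Z), ncol(x$Z), x$lambda_mfp, x$I0,
              min(x$Z[fin]), max(x$Z[fin]), sum(x$opaque)))
  invisible(x)
}

#' @export
plot.thickness_map <- function(x, ...) {
  Z <- x$Z
  Z[!is.finite(Z)] <- max(Z[is.finite(Z)])
  graphics::image(t(Z)[, rev(seq_len(nrow(Z)))],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = nrow(Z) / ncol(Z),
                  main = "thickness (nm)", ...)
  invisible(x)
}
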