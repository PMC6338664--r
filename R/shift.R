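# Diffraction-shift correction.
#
# Beam scanning drags the whole diffraction pattern across the detector.
# Single frames are too noisy to track, so frames are averaged strip-wise
# along one scan direction at a time, the centre of mass of the
# transmitted beam is measured per strip, and every frame in the strip is
# translated (integer pixels, preserving counting statistics) to a common
# centre; the two scan directions are corrected separately and the pair of
# passes is iterated when drift couples them.

# dense frame at scan position (iy, ix), for either container
.frame_dense <- function(scan, iy, ix) {
  if (inherits(scan, "scan4d")) scan$data[iy, ix, , ]
  else densify_pattern(sparse_frame(scan, iy, ix))
}

.scan_shape <- function(scan) {
  if (inherits(scan, "scan4d")) dim(scan$data)[1:2] else scan$shape
}
.frame_shape <- function(scan) {
  if (inherits(scan, "scan4d")) dim(scan$data)[3:4] else scan$frame_shape
}

# centre of mass inside a disc about a running centre (3 refinements);
# an unwindowed COM would be biased by Bragg peaks
com_in_disc <- function(frame, centre, radius) {
  ii <- row(frame); jj <- col(frame)
  for (it in 1:3) {
    w <- frame * ((ii - centre[1])^2 + (jj - centre[2])^2 <= radius^2)
    s <- sum(w)
    if (s <= 0) return(c(NA_real_, NA_real_))
    centre <- c(sum(w * ii), sum(w * jj)) / s
  }
  centre
}

#' Strip-wise centre of mass of the transmitted beam
#'
#' Averages all patterns along the scan axis orthogonal to `axis` (e.g.
#' for a 72 x 50 scan and `axis = "scan_x"`, 50 strip averages) and
#' returns the central-beam centre of mass of each strip average. Empty
#' strips are interpolated from their neighbours.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param axis which scan index labels the strips.
#' @param beam_radius radius (pixels) of the central disc; the COM window
#'   is 1.5 x this radius.
#' @return matrix with one row per strip, columns `com_y`, `com_x`.
#' @export
stripwise_com <- function(scan, axis = c("scan_x", "scan_y"), beam_radius) {
  axis <- match.arg(axis)
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  centre <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2)
  n_strips <- if (axis == "scan_x") sh[2] else sh[1]
  out <- matrix(NA_real_, n_strips, 2,
                dimnames = list(NULL, c("com_y", "com_x")))
  for (s in seq_len(n_strips)) {
    acc <- matrix(0, fs[1], fs[2])
    if (axis == "scan_x") {
      for (iy in seq_len(sh[1])) acc <- acc + .frame_dense(scan, iy, s)
    } else {
      for (ix in seq_len(sh[2])) acc <- acc + .frame_dense(scan, s, ix)
    }
    out[s, ] <- com_in_disc(acc, centre, 1.5 * beam_radius)
  }
  for (j in 1:2) {
    bad <- is.na(out[, j])
    if (any(bad)) {
      if (all(bad)) stop("all strips empty; cannot track the beam")
      out[bad, j] <- stats::approx(which(!bad), out[!bad, j],
                                   xout = which(bad), rule = 2)$y
    }
  }
  out
}

# translate one frame by integer (dy, dx); entries shifted out are dropped
translate_pattern <- function(p, dy, dx) {
  shape <- attr(p, "frame_shape")
  if (nrow(p) == 0L || (dy == 0L && dx == 0L)) return(p)
  ky <- p[, 1] + dy; kx <- p[, 2] + dx
  keep <- ky >= 1 & ky <= shape[1] & kx >= 1 & kx <= shape[2]
  structure(cbind(k_y = ky[keep], k_x = kx[keep],
                  count = p[keep, 3]),
            frame_shape = shape, class = "sparse_pattern")
}

translate_dense <- function(M, dy, dx) {
  out <- matrix(0, nrow(M), ncol(M))
  ys <- seq_len(nrow(M)); xs <- seq_len(ncol(M))
  yd <- ys + dy; xd <- xs + dx
  oky <- yd >= 1 & yd <= nrow(M); okx <- xd >= 1 & xd <= ncol(M)
  out[yd[oky], xd[okx]] <- M[ys[oky], xs[okx]]
  out
}

#' Correct scan-induced diffraction shifts
#'
#' Separable strip-wise recentring: per strip along one scan axis, the
#' integer-pixel shift bringing the strip's central-beam centre of mass to
#' the geometric frame centre is applied to all its frames; then the other
#' axis; the pass pair repeats until the residual strip COM deviation
#' drops below `tol` pixels or `max_rounds` is reached.
#'
#' @param scan a `scan4d` or `sparse_scan`.
#' @param beam_radius central-disc radius in pixels.
#' @param max_rounds maximum number of axis-pair rounds (>= 1).
#' @param order which scan axis to correct first.
#' @param tol convergence tolerance on the residual COM deviation, pixels.
#' @return list with `scan` (corrected, same class as input) and `shifts`
#'   (`shift_field`: per-position `dy`, `dx` totals in detector pixels,
#'   `n_rounds`, `residual`).
#' @export
correct_shifts <- function(scan, beam_radius, max_rounds = 3,
                           order = c("scan_y", "scan_x"), tol = 0.5) {
  stopifnot(max_rounds >= 1)
  order <- match.arg(order, c("scan_y", "scan_x"), several.ok = TRUE)
  if (length(order) == 1L) order <- c(order, setdiff(c("scan_y", "scan_x"), order))
  sh <- .scan_shape(scan); fs <- .frame_shape(scan)
  centre <- c((fs[1] + 1) / 2, (fs[2] + 1) / 2)
  dy <- matrix(0L, sh[1], sh[2]); dx <- matrix(0L, sh[1], sh[2])
  sparse <- inherits(scan, "sparse_scan")

  apply_strip <- function(axis, s, sy, sx) {
    if (axis == "scan_x") { iys <- seq_len(sh[1]); ixs <- s }
    else { iys <- s; ixs <- seq_len(sh[2]) }
    for (iy in iys) for (ix in ixs) {
      if (sparse) {
        k <- iy + (ix - 1L) * sh[1]
        scan$frames[[k]] <<- translate_pattern(scan$frames[[k]], sy, sx)
      } else {
        scan$data[iy, ix, , ] <<- translate_dense(scan$data[iy, ix, , ], sy, sx)
      }
      dy[iy, ix] <<- dy[iy, ix] + sy
      dx[iy, ix] <<- dx[iy, ix] + sx
    }
  }

  residual <- Inf
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    for (axis in order) {
      coms <- stripwise_com(scan, axis, beam_radius)
      for (s in seq_len(nrow(coms))) {
        sy <- as.integer(round(centre[1] - coms[s, 1]))
        sx <- as.integer(round(centre[2] - coms[s, 2]))
        if (sy != 0L || sx != 0L) apply_strip(axis, s, sy, sx)
      }
    }
    residual <- max(abs(sweep(stripwise_com(scan, "scan_x", beam_radius), 2, centre)),
                    abs(sweep(stripwise_com(scan, "scan_y", beam_radius), 2, centre)))
    if (residual < tol) break
  }
  if (residual >= tol)
    warning(sprintf("shift correction did not converge: residual %.2f px after %d round(s)",
                    residual, rounds))
  if (sparse) {
    for (ix in seq_len(sh[2])) for (iy in seq_len(sh[1]))
      scan$totals[iy, ix] <- sum(sparse_frame(scan, iy, ix)[, 3])
  }
  list(scan = scan,
       shifts = structure(list(dy = dy, dx = dx, n_rounds = rounds,
                               residual = residual),
                          class = "shift_field"))
}

#' @export
print.shift_field <- function(x, ...) {
  cat(sprintf("shift field: %d round(s), residual %.3f px, |dy|<=%d |dx|<=%d\n",
              x$n_rounds, x$residual, max(abs(x$dy)), max(abs(x$dx))))
  invisible(x)
}
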