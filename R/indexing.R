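# Library-based orientation indexing.
#
# Each cluster-average pattern is assigned a lattice orientation (x/y tilt
# away from the mean orientation) and thickness by comparing max-scaled
# peak intensities against a simulated template library on a common peak
# set, using RMSD over all peak positions:
#   RMSD_ij = sqrt( sum_p (mu_i_p - Sim_j_p)^2 / P )
# The library spans a regular tilt grid (+/-4 degrees in 0.25-degree
# increments by protocol) crossed with a thickness range (10-600 nm).

#' Enumerate candidate peak positions
#'
#' Detector positions of every reflection that can be excited anywhere in
#' the library's tilt range, excluding the central disc: the common peak
#' set over which all intensity lists are extracted and compared.
#'
#' @param cell a [unit_cell()].
#' @param detector a [detector_model()].
#' @param mean_orientation (tilt_x, tilt_y) of the scan's mean orientation
#'   in degrees; the library is centred here.
#' @param tilt_range half-width of the tilt library, degrees.
#' @param max_resolution resolution cutoff, ångström.
#' @param exclusion_radius central-disc exclusion radius in pixels
#'   (default 2 x the beam radius).
#' @param min_thickness thinnest library entry, nm; sets how far from the
#'   Ewald sphere a reflection may sit and still be counted as reachable.
#' @return object of class `peak_set`: integer n x 2 position matrix
#'   (`k_y`, `k_x`) with attributes `hkl` and `integration_radius`.
#' @export
enumerate_peaks <- function(cell, detector = detector_model(),
                            mean_orientation = c(0, 0), tilt_range = 4,
                            max_resolution = 1.4, exclusion_radius = NULL,
                            min_thickness = 10) {
  if (is.null(exclusion_radius)) exclusion_radius <- 2 * detector$beam_radius_px
  refl <- enumerate_reflections(cell, max_resolution)
  g <- rot_y(mean_orientation[2]) %*% rot_x(mean_orientation[1]) %*% refl$g
  lam <- ELECTRON_WAVELENGTH_300KV
  s0 <- abs(-g[3, ] - lam * colSums(g^2) / 2)
  gmag <- sqrt(colSums(g^2))
  # a tilt of t degrees moves the excitation error by at most |g| sin(t);
  # reachability is symmetrised over Friedel mates, whose excitation
  # errors differ only by the Ewald-sphere curvature term
  reach <- pmax(0, s0 - gmag * sinpi(tilt_range / 180))
  key <- paste(refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3])
  mate <- match(paste(-refl$hkl[, 1], -refl$hkl[, 2], -refl$hkl[, 3]), key)
  reach <- pmin(reach, reach[mate], na.rm = TRUE)
  excitable <- reach < 4 * relrod_sigma(min_thickness)
  ctr <- detector_centre(detector)
  py <- round(ctr[1] + detector$px_per_invA * g[2, ])
  px <- round(ctr[2] + detector$px_per_invA * g[1, ])
  keep <- excitable &
    py >= 1 & py <= detector$n_ky & px >= 1 & px <= detector$n_kx &
    (py - ctr[1])^2 + (px - ctr[2])^2 > exclusion_radius^2
  pos <- cbind(k_y = py, k_x = px)[keep, , drop = FALSE]
  hkl <- refl$hkl[keep, , drop = FALSE]
  dup <- duplicated(pos)
  pos <- pos[!dup, , drop = FALSE]
  hkl <- hkl[!dup, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop("empty peak set: detector/exclusion geometry admits no reflection")
  structure(pos, hkl = hkl, integration_radius = 4,
            exclusion_radius = exclusion_radius,
            mean_orientation = mean_orientation, class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak set: %d positions, integration radius %d px, exclusion %g px\n",
              nrow(x), attr(x, "integration_radius"),
              attr(x, "exclusion_radius")))
  invisible(x)
}

#' Max-scaled peak intensities of a pattern
#'
#' Integrates all pixel values within `integration_radius` pixels of each
#' peak position (a pixel claimed by two discs is credited to the nearer
#' peak) and scales the list by its maximum, so the strongest peak reads
#' 1. An all-zero list is returned with attribute `flagged = TRUE`.
#'
#' @param pattern a `sparse_pattern` or dense matrix.
#' @param peaks a [enumerate_peaks()] set.
#' @param integration_radius integration radius in pixels (default the
#'   peak set's, 4).
#' @return numeric vector of length `nrow(peaks)`.
#' @export
extract_scaled_intensities <- function(pattern, peaks,
                                       integration_radius = NULL) {
  if (is.null(integration_radius))
    integration_radius <- attr(peaks, "integration_radius")
  if (is.matrix(pattern) && !inherits(pattern, "sparse_pattern")) {
    nz <- which(pattern != 0, arr.ind = TRUE)
    entries <- cbind(nz, pattern[nz])
  } else entries <- unclass(pattern)
  vals <- numeric(nrow(peaks))
  if (nrow(entries)) {
    d2 <- outer(entries[, 1], peaks[, 1], "-")^2 +
      outer(entries[, 2], peaks[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    inside <- d2[cbind(seq_len(nrow(entries)), nearest)] <= integration_radius^2
    if (any(inside)) {
      sums <- rowsum(entries[inside, 3], nearest[inside])
      vals[as.integer(rownames(sums))] <- sums
    }
  }
  if (max(vals) > 0) vals / max(vals)
  else structure(vals, flagged = TRUE)
}

#' Build a simulated template library
#'
#' Kinematic peak-intensity templates over a regular (tilt_x, tilt_y)
#' grid crossed with a set of thicknesses, all extracted on a common peak
#' set and max-scaled. Entries store intensity lists rather than frames;
#' [render_library_entry()] materialises any entry's full pattern.
#'
#' @param cell a [unit_cell()].
#' @param detector a [detector_model()].
#' @param peaks the [enumerate_peaks()] set shared with the experimental
#'   patterns.
#' @param tilt_range half-width of the tilt grid, degrees.
#' @param tilt_step grid increment, degrees (0.25 by protocol).
#' @param thicknesses thickness values in nm (protocol range 10-600 nm).
#' @param mean_orientation grid centre, degrees.
#' @param max_resolution,bragg_strength,amplitudes passed to the kinematic
#'   engine.
#' @return object of class `template_library`: list with `entries`
#'   (data.frame tilt_x, tilt_y, thickness), `intensities` (entries x
#'   peaks matrix), `peaks`, `cell`, `detector`.
#' @export
build_template_library <- function(cell, detector = detector_model(), peaks,
                                   tilt_range = 4, tilt_step = 0.25,
                                   thicknesses = c(10, 100, 300, 600),
                                   mean_orientation = c(0, 0),
                                   max_resolution = 1.4,
                                   bragg_strength = 0.01,
                                   amplitudes = NULL) {
  tilts <- seq(-tilt_range, tilt_range, by = tilt_step)
  entries <- expand.grid(tilt_x = tilts, tilt_y = tilts,
                         thickness = thicknesses,
                         KEEP.OUT.ATTRS = FALSE)
  r_int <- attr(peaks, "integration_radius")
  E <- matrix(0, nrow(entries), nrow(peaks))
  for (i in seq_len(nrow(entries))) {
    pts <- kinematic_points(cell,
                            mean_orientation + c(entries$tilt_x[i],
                                                 entries$tilt_y[i]),
                            entries$thickness[i], detector,
                            max_resolution, bragg_strength, amplitudes)
    if (nrow(pts$positions) == 0L) next
    d2 <- outer(pts$positions[, 1], peaks[, 1], "-")^2 +
      outer(pts$positions[, 2], peaks[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    inside <- d2[cbind(seq_along(nearest), nearest)] <= r_int^2
    if (any(inside)) {
      sums <- rowsum(pts$intensity[inside], nearest[inside])
      E[i, as.integer(rownames(sums))] <- sums
    }
    m <- max(E[i, ])
    if (m > 0) E[i, ] <- E[i, ] / m
  }
  structure(list(entries = entries, intensities = E, peaks = peaks,
                 cell = cell, detector = detector,
                 tilt_range = tilt_range, tilt_step = tilt_step,
                 mean_orientation = mean_orientation,
                 max_resolution = max_resolution,
                 bragg_strength = bragg_strength),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("template library: %d entries (tilt +/-%g deg step %g, %d thickness values), %d peaks\n",
              nrow(x$entries), x$tilt_range, x$tilt_step,
              length(unique(x$entries$thickness)), nrow(x$peaks)))
  invisible(x)
}

#' Render the full frame of one library entry
#' @param library a [build_template_library()] result.
#' @param i entry index.
#' @return dense expected-intensity frame.
#' @export
render_library_entry <- function(library, i) {
  e <- library$entries[i, ]
  kinematic_pattern(library$cell,
                    library$mean_orientation + c(e$tilt_x, e$tilt_y),
                    e$thickness, library$detector,
                    library$max_resolution, library$bragg_strength)
}

#' Match a pattern against the template library
#'
#' RMSD between the pattern's max-scaled peak intensities and every
#' library entry's, over the common peak set; the entry with the lowest
#' RMSD wins. Exact ties are broken toward smaller |tilt|, then smaller
#' thickness. An all-zero intensity list is returned as unindexable.
#'
#' @param pattern a pattern (sparse or dense), or a numeric intensity
#'   vector already extracted on the library's peak set.
#' @param library a [build_template_library()] result.
#' @return list with `tilt_x`, `tilt_y`, `thickness`, `rmsd`,
#'   `rmsd_runner_up`, `index`, `unindexable`.
#' @export
rmsd_match <- function(pattern, library) {
  x <- if (is.numeric(pattern) && is.null(dim(pattern)) &&
           !inherits(pattern, "sparse_pattern"))
    pattern
  else extract_scaled_intensities(pattern, library$peaks)
  if (isTRUE(attr(x, "flagged")) || max(x) == 0)
    return(list(tilt_x = NA_real_, tilt_y = NA_real_,
                thickness = NA_real_, rmsd = NA_real_,
                rmsd_runner_up = NA_real_, index = NA_integer_,
                unindexable = TRUE))
  stopifnot(length(x) == ncol(library$intensities))
  rmsd <- sqrt(rowMeans(sweep(library$intensities, 2, as.numeric(x))^2))
  tilt2 <- library$entries$tilt_x^2 + library$entries$tilt_y^2
  ord <- order(rmsd, tilt2, library$entries$thickness)
  best <- ord[1]
  list(tilt_x = library$entries$tilt_x[best],
       tilt_y = library$entries$tilt_y[best],
       thickness = library$entries$thickness[best],
       rmsd = rmsd[best],
       rmsd_runner_up = if (length(ord) > 1) rmsd[ord[2]] else NA_real_,
       index = best, unindexable = FALSE)
}

#' Index all cluster averages
#'
#' Runs [rmsd_match()] on every cluster-average pattern and derives the
#' scan's mean orientation as the RMSD-weighted mean of the per-cluster
#' assignments (weights 1/(rmsd + 1e-6)), plus each cluster's tilt
#' deviation from it.
#'
#' @param cluster_means list of average patterns (from
#'   [cluster_spatial_map()]).
#' @param library a [build_template_library()] result.
#' @return object of class `orientation_result`: data.frame `per_cluster`
#'   (tilt_x, tilt_y, thickness, rmsd, rmsd_runner_up, delta_x, delta_y,
#'   unindexable) and `mean_orientation`.
#' @export
index_clusters <- function(cluster_means, library) {
  res <- lapply(cluster_means, rmsd_match, library = library)
  tab <- do.call(rbind, lapply(res, function(r)
    data.frame(tilt_x = r$tilt_x, tilt_y = r$tilt_y,
               thickness = r$thickness, rmsd = r$rmsd,
               rmsd_runner_up = r$rmsd_runner_up,
               unindexable = r$unindexable)))
  ok <- !tab$unindexable
  if (any(ok)) {
    w <- 1 / (tab$rmsd[ok] + 1e-6)
    mo <- c(sum(w * tab$tilt_x[ok]), sum(w * tab$tilt_y[ok])) / sum(w)
  } else mo <- c(NA_real_, NA_real_)
  tab$delta_x <- tab$tilt_x - mo[1]
  tab$delta_y <- tab$tilt_y - mo[2]
  structure(list(per_cluster = tab, mean_orientation = mo),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("orientation result: %d clusters (%d unindexable), mean orientation (%.2f, %.2f) deg\n",
              nrow(x$per_cluster), sum(x$per_cluster$unindexable),
              x$mean_orientation[1], x$mean_orientation[2]))
  print(x$per_cluster, digits = 3)
  invisible(x)
}

#' Orientation deviation map with colour-wheel rendering
#'
#' Spreads each cluster's tilt deviation from the mean orientation over
#' its scan positions and renders the two-channel tilt field as an
#' HSV colour wheel: hue = tilt direction, saturation = magnitude
#' (`max_tilt` degrees = full saturation). Unindexable clusters render as
#' neutral grey.
#'
#' @param results an [index_clusters()] result.
#' @param label_map cluster label matrix from [cluster_spatial_map()].
#' @param max_tilt full-scale tilt magnitude in degrees (4, as in the
#'   colour wheel of the published-style maps).
#' @return list with `delta_x`, `delta_y` (matrices, degrees) and `rgb`
#'   (scan_y x scan_x x 3 array in [0, 1]).
#' @export
orientation_map <- function(results, label_map, max_tilt = 4) {
  tab <- results$per_cluster
  sh <- dim(label_map)
  dxm <- matrix(NA_real_, sh[1], sh[2]); dym <- dxm
  rgb <- array(0.5, c(sh, 3))        # neutral grey for unindexable
  for (k in seq_len(nrow(tab))) {
    sel <- label_map == k
    if (tab$unindexable[k]) next
    dxm[sel] <- tab$delta_x[k]; dym[sel] <- tab$delta_y[k]
    mag <- sqrt(tab$delta_x[k]^2 + tab$delta_y[k]^2)
    hue <- (atan2(tab$delta_y[k], tab$delta_x[k]) / (2 * pi)) %% 1
    col <- grDevices::hsv(hue, min(1, mag / max_tilt), 1)
    v <- grDevices::col2rgb(col) / 255
    for (ch in 1:3) { tmp <- rgb[, , ch]; tmp[sel] <- v[ch]; rgb[, , ch] <- tmp }
  }
  list(delta_x = dxm, delta_y = dym, rgb = rgb)
}

#' Plot an orientation map
#' @param map an [orientation_map()] result.
#' @param ... passed to [graphics::rasterImage()].
#' @export
plot_orientation_map <- function(map, ...) {
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(map$rgb)[1] / dim(map$rgb)[2])
  graphics::rasterImage(grDevices::as.raster(map$rgb), 0, 0, 1, 1,
                        interpolate = FALSE, ...)
  invisible(map)
}
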