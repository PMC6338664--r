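# Kinematic diffraction simulator.
#
# Template libraries and synthetic scans are generated from a kinematic
# model: reciprocal-lattice points are projected onto the detector and
# weighted by a Gaussian excitation-error envelope whose width scales as
# 1/thickness (the relrod of a finite crystal). Structure factors default
# to uniform; an amplitude table can be supplied. Inelastic loss is a
# single exp(-Z/lambda) attenuation of the whole elastic pattern, shared
# with the thickness module so the log-ratio round-trip closes.

# electron wavelength at 300 keV, in angstrom
ELECTRON_WAVELENGTH_300KV <- 0.0196875

#' Kinematic diffraction pattern
#'
#' Expected (noise-free) diffraction intensity for a crystal of given
#' orientation and thickness. The frame is normalised so that its total
#' equals the fraction of probe electrons reaching the detector,
#' `exp(-thickness / lambda_mfp)`; the (000) disc holds the transmitted
#' beam and is the unique global maximum.
#'
#' @param cell a [unit_cell()].
#' @param tilt length-2 numeric, (tilt_x, tilt_y) of the lattice away from
#'   the zone in degrees; magnitudes must be <= 10.
#' @param thickness crystal thickness in nm; 0 means vacuum (central beam
#'   only, no attenuation).
#' @param detector a [detector_model()].
#' @param max_resolution resolution cutoff in ångström for enumerating
#'   reflections.
#' @param bragg_strength peak kinematic intensity of a fully excited
#'   reflection relative to the transmitted beam.
#' @param lambda_mfp inelastic mean free path in nm used for the
#'   attenuation factor.
#' @param amplitudes optional data frame with columns `h`, `k`, `l`, `amp`
#'   giving per-reflection structure-factor amplitudes (default uniform 1).
#' @param mosaic_sigma_deg angular width (degrees) of the rocking-profile
#'   broadening from beam convergence and the orientation spread inside
#'   one probe position; adds `|g| * sin(sigma)` in quadrature to the
#'   relrod width.
#' @param spot_sigma Gaussian footprint of a Bragg spot on the detector,
#'   pixels.
#' @param as_points if TRUE, return the reflection point list (positions,
#'   intensities, excitation errors, hkl) instead of a rendered frame;
#'   used by the template-library builder.
#' @return a `n_ky x n_kx` non-negative matrix (or a point list).
#' @export
kinematic_pattern <- function(cell, tilt = c(0, 0), thickness,
                              detector = detector_model(),
                              max_resolution = 1.4,
                              bragg_strength = 0.01,
                              lambda_mfp = 332,
                              amplitudes = NULL,
                              mosaic_sigma_deg = 0.2,
                              spot_sigma = 1.2,
                              as_points = FALSE) {
  if (!inherits(cell, "unit_cell")) stop("invalid cell: not a unit_cell")
  stopifnot(length(tilt) == 2, max_resolution > 0, thickness >= 0)
  if (any(abs(tilt) > 10)) stop("tilt magnitudes must be <= 10 degrees")

  pts <- kinematic_points(cell, tilt, thickness, detector, max_resolution,
                          bragg_strength, amplitudes, mosaic_sigma_deg)
  if (as_points) return(pts)

  frame <- central_disc_frame(detector)
  if (thickness > 0) {
    if (nrow(pts$positions) == 0L)
      warning("no reflections fall within the detector (empty pattern)")
    frame <- frame + spot_frame(pts$positions, pts$intensity,
                                detector, spot_sigma)
    frame <- frame / sum(frame) * exp(-thickness / lambda_mfp)
  }
  frame
}

# reflection point list for one orientation/thickness; positions are
# (row, col) detector pixels (1-based, fractional), intensities relative
# to a unit transmitted beam
kinematic_points <- function(cell, tilt, thickness, detector,
                             max_resolution, bragg_strength,
                             amplitudes = NULL, mosaic_sigma_deg = 0.2) {
  refl <- enumerate_reflections(cell, max_resolution)
  if (thickness <= 0 || nrow(refl$hkl) == 0L) {
    return(list(positions = matrix(0, 0, 2), intensity = numeric(0),
                s = numeric(0), hkl = refl$hkl[0, , drop = FALSE]))
  }
  g <- rot_y(tilt[2]) %*% rot_x(tilt[1]) %*% refl$g
  lam <- ELECTRON_WAVELENGTH_300KV
  # excitation error for a beam along +z: s = -g_z - lambda |g|^2 / 2
  s <- -g[3, ] - lam * colSums(g^2) / 2
  sigma_s <- sqrt(relrod_sigma(thickness)^2 +
                    (sqrt(colSums(g^2)) * sinpi(mosaic_sigma_deg / 180))^2)
  w <- exp(-s^2 / (2 * sigma_s^2))

  amp <- rep(1, ncol(g))
  if (!is.null(amplitudes)) {
    key <- paste(refl$hkl[, 1], refl$hkl[, 2], refl$hkl[, 3])
    tab <- stats::setNames(amplitudes$amp,
                           paste(amplitudes$h, amplitudes$k, amplitudes$l))
    hit <- key %in% names(tab)
    amp[hit] <- tab[key[hit]]
  }
  intensity <- bragg_strength * amp^2 * w

  ctr <- detector_centre(detector)
  py <- ctr[1] + detector$px_per_invA * g[2, ]
  px <- ctr[2] + detector$px_per_invA * g[1, ]
  keep <- intensity > 1e-8 &
    py >= 1 & py <= detector$n_ky & px >= 1 & px <= detector$n_kx
  list(positions = cbind(py, px)[keep, , drop = FALSE],
       intensity = intensity[keep],
       s = s[keep],
       hkl = refl$hkl[keep, , drop = FALSE])
}

# relrod width (A^-1) of a crystal `thickness` nm thick
relrod_sigma <- function(thickness) 1 / (10 * max(thickness, 10))

# unit-integral uniform disc for the focused central beam
central_disc_frame <- function(detector) {
  ctr <- detector_centre(detector)
  r <- detector$beam_radius_px
  rows <- max(1L, floor(ctr[1] - r)):min(detector$n_ky, ceiling(ctr[1] + r))
  cols <- max(1L, floor(ctr[2] - r)):min(detector$n_kx, ceiling(ctr[2] + r))
  frame <- matrix(0, detector$n_ky, detector$n_kx)
  d2 <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+")
  inside <- d2 <= r^2
  frame[rows, cols][inside] <- 1
  frame / sum(frame)
}

# accumulate Gaussian spots of total weight `intensity` at fractional
# pixel positions
spot_frame <- function(positions, intensity, detector, spot_sigma) {
  frame <- matrix(0, detector$n_ky, detector$n_kx)
  if (nrow(positions) == 0L) return(frame)
  m <- ceiling(3 * spot_sigma)
  off <- -m:m
  for (i in seq_len(nrow(positions))) {
    ry <- round(positions[i, 1]) + off
    rx <- round(positions[i, 2]) + off
    oky <- ry >= 1 & ry <= detector$n_ky
    okx <- rx >= 1 & rx <= detector$n_kx
    if (!any(oky) || !any(okx)) next
    wy <- stats::dnorm(ry[oky], positions[i, 1], spot_sigma)
    wx <- stats::dnorm(rx[okx], positions[i, 2], spot_sigma)
    patch <- outer(wy, wx)
    frame[ry[oky], rx[okx]] <- frame[ry[oky], rx[okx]] +
      intensity[i] * patch / sum(patch)
  }
  frame
}

# separable Gaussian blur with zero padding (detector point spread)
gaussian_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  m <- ceiling(3 * sigma)
  k <- stats::dnorm(-m:m, sd = sigma)
  k <- k / sum(k)
  shift_rows <- function(A, o) {
    B <- matrix(0, nrow(A), ncol(A))
    if (o >= 0) B[seq_len(nrow(A) - o) + o, ] <- A[seq_len(nrow(A) - o), ]
    else B[seq_len(nrow(A) + o), ] <- A[seq_len(nrow(A) + o) - o, ]
    B
  }
  out <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(k)) out <- out + k[j] * shift_rows(M, j - m - 1L)
  out2 <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(k)) out2 <- out2 + k[j] * t(shift_rows(t(out), j - m - 1L))
  out2
}

#' Render a raw analog detector frame
#'
#' Draws Poisson electron arrivals on an expected-intensity frame, deposits
#' Gamma-distributed charge per electron, applies the detector point
#' spread, and adds strip dark offsets and Gaussian read noise — the
#' analog signal that hybrid counting consumes. Fully deterministic given
#' `seed`.
#'
#' @param expected non-negative expected frame whose sum is the fraction
#'   of probe electrons reaching the detector (as produced by
#'   [kinematic_pattern()]).
#' @param probe a [probe_model()]; `electron_rate * dwell_s` electrons are
#'   scattered over the frame.
#' @param detector a [detector_model()].
#' @param seed integer seed; required (reproducibility contract).
#' @param return_electrons if TRUE, attach the Poisson electron-count map
#'   as attribute `"electrons"` (ground truth for counting tests).
#' @return numeric matrix of analog counts.
#' @export
render_detector <- function(expected, probe, detector, seed,
                            return_electrons = FALSE) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (any(expected < 0)) stop("expected frame must be non-negative")
  stopifnot(nrow(expected) == detector$n_ky, ncol(expected) == detector$n_kx)
  set.seed(as.integer(seed))
  n_e <- probe$electron_rate * probe$dwell_s
  electrons <- matrix(stats::rpois(length(expected), expected * n_e),
                      nrow(expected))
  deposited <- matrix(0, nrow(expected), ncol(expected))
  hit <- which(electrons > 0L)
  if (length(hit)) {
    sh <- detector$gain_shape
    deposited[hit] <- stats::rgamma(length(hit),
                                    shape = electrons[hit] * sh,
                                    rate = sh / detector$single_electron_gain)
  }
  if (detector$psf_sigma > 0)
    deposited <- gaussian_blur(deposited, detector$psf_sigma)
  offs <- detector$strip_offsets[strip_of_column(detector)]
  frame <- deposited +
    matrix(offs, nrow(expected), ncol(expected), byrow = TRUE) +
    matrix(stats::rnorm(length(expected), 0, detector$read_noise_sigma),
           nrow(expected))
  if (return_electrons) attr(frame, "electrons") <- electrons
  frame
}

#' Generate a synthetic 4D-STEM scan
#'
#' Renders one diffraction frame per scan position from a
#' [crystal_phantom()]: crystal positions get the kinematic pattern for
#' that position's tilt and thickness, carbon support an attenuated
#' central beam, vacuum the unattenuated beam. Ground truth (tilt fields,
#' thickness, domain labels, per-frame deposited electrons) travels with
#' the scan under `$truth`.
#'
#' @param phantom a [crystal_phantom()].
#' @param probe a [probe_model()].
#' @param detector a [detector_model()].
#' @param seed integer seed (required when `noise = TRUE`).
#' @param noise if FALSE, frames are the noise-free expected intensities
#'   scaled to electrons per step (no detector response, no offsets).
#' @param lambda_mfp inelastic mean free path, nm.
#' @param max_resolution,bragg_strength,spot_sigma passed to
#'   [kinematic_pattern()].
#' @return object of class `scan4d`: list with `data` (4-D array
#'   scan_y x scan_x x k_y x k_x), `meta`, `truth`.
#' @export
generate_scan <- function(phantom, probe = probe_model(),
                          detector = detector_model(), seed = NULL,
                          noise = TRUE, lambda_mfp = 332,
                          max_resolution = 1.4, bragg_strength = 0.01,
                          spot_sigma = 1.2) {
  if (noise && is.null(seed)) stop("seed is required")
  dm <- phantom$dim
  n_e <- probe$electron_rate * probe$dwell_s
  data <- array(0, c(dm[1], dm[2], detector$n_ky, detector$n_kx))
  electrons <- matrix(NA_real_, dm[1], dm[2])
  if (!is.null(seed)) set.seed(as.integer(seed))
  frame_seeds <- if (noise) sample.int(2147483646L, prod(dm)) else NULL
  cache <- new.env(parent = emptyenv())
  idx <- 0L
  for (ix in seq_len(dm[2])) for (iy in seq_len(dm[1])) {
    idx <- iy + (ix - 1L) * dm[1]
    lab <- phantom$labels[iy, ix]
    th <- phantom$thickness[iy, ix]
    key <- sprintf("%s|%.4f|%.4f|%.3f", lab,
                   phantom$tilt_x[iy, ix], phantom$tilt_y[iy, ix], th)
    expected <- cache[[key]]
    if (is.null(expected)) {
      expected <- if (lab == "crystal") {
        kinematic_pattern(phantom$cell,
                          c(phantom$tilt_x[iy, ix], phantom$tilt_y[iy, ix]),
                          th, detector, max_resolution, bragg_strength,
                          lambda_mfp, spot_sigma = spot_sigma)
      } else {
        # carbon: amorphous support attenuates but does not diffract
        central_disc_frame(detector) * exp(-th / lambda_mfp)
      }
      cache[[key]] <- expected
    }
    if (noise) {
      fr <- render_detector(expected, probe, detector,
                            seed = frame_seeds[idx], return_electrons = TRUE)
      electrons[iy, ix] <- sum(attr(fr, "electrons"))
      attr(fr, "electrons") <- NULL
      data[iy, ix, , ] <- fr
    } else {
      data[iy, ix, , ] <- expected * n_e
      electrons[iy, ix] <- sum(expected) * n_e
    }
  }
  structure(list(
    data = data,
    meta = list(cell = phantom$cell, probe = probe, detector = detector,
                lambda_mfp = lambda_mfp, step_nm = probe$step_nm,
                dwell_s = probe$dwell_s, noise = noise, seed = seed),
    truth = list(tilt_x = phantom$tilt_x, tilt_y = phantom$tilt_y,
                 thickness = phantom$thickness, labels = phantom$labels,
                 domains = phantom$domains, electrons = electrons)),
    class = "scan4d")
}

#' @export
print.scan4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("4DSTEM scan: %d x %d positions, %d x %d detector%s\n",
              d[1], d[2], d[3], d[4],
              if (isTRUE(x$meta$noise)) "" else " (noise-free)"))
  invisible(x)
}

#' @export
dim.scan4d <- function(x) dim(x$data)
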