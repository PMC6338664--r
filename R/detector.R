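#' Detector model
#'
#' Geometry and response of the pixelated direct electron detector.
#' The full-frame instrument is 1792 x 1920 pixels; the package default is
#' a desk-scale 256 x 272 detector with the same strip readout structure,
#' chosen so whole synthetic scans fit comfortably in memory.
#'
#' @param n_ky,n_kx detector dimensions in pixels (rows, columns).
#' @param strip_width width (columns) of one dark-current readout strip;
#'   the last strip may be partial.
#' @param strip_offsets per-strip dark-current offset in counts; recycled
#'   or generated if a single value / NULL is given.
#' @param read_noise_sigma Gaussian readout noise, counts.
#' @param single_electron_gain mean counts deposited per primary electron.
#' @param gain_shape shape parameter of the per-event Gamma gain spread;
#'   larger = narrower pulse-height distribution.
#' @param psf_sigma detector point-spread sigma in pixels (0 = charge
#'   confined to one pixel, the counting-mode operating point).
#' @param px_per_invA camera-length calibration, pixels per reciprocal
#'   ångström.
#' @param beam_radius_px radius of the focused central (000) disc, pixels.
#' @return object of class `detector_model`.
#' @export
detector_model <- function(n_ky = 256L, n_kx = 272L,
                           strip_width = 32L,
                           strip_offsets = NULL,
                           read_noise_sigma = 2,
                           single_electron_gain = 15,
                           gain_shape = 400,
                           psf_sigma = 0,
                           px_per_invA = 170,
                           beam_radius_px = 5) {
  stopifnot(n_ky > 0, n_kx > 0, strip_width > 0,
            single_electron_gain > 0, read_noise_sigma >= 0,
            psf_sigma >= 0, px_per_invA > 0, beam_radius_px > 0)
  n_strips <- ceiling(n_kx / strip_width)
  if (is.null(strip_offsets)) {
    # deterministic but strip-dependent baseline, like K2 readout banks
    strip_offsets <- 10 + 5 * ((seq_len(n_strips) * 7L) %% 5L)
  }
  strip_offsets <- rep_len(as.numeric(strip_offsets), n_strips)
  structure(list(n_ky = as.integer(n_ky), n_kx = as.integer(n_kx),
                 strip_width = as.integer(strip_width),
                 strip_offsets = strip_offsets,
                 read_noise_sigma = read_noise_sigma,
                 single_electron_gain = single_electron_gain,
                 gain_shape = gain_shape,
                 psf_sigma = psf_sigma,
                 px_per_invA = px_per_invA,
                 beam_radius_px = beam_radius_px),
            class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("detector: %d x %d px, %d strips of %d cols, gain %.1f counts/e-, read noise %.1f\n",
              x$n_ky, x$n_kx, length(x$strip_offsets), x$strip_width,
              x$single_electron_gain, x$read_noise_sigma))
  invisible(x)
}

#' Scanned probe model
#'
#' Probe and scan parameters. Defaults are the experimental operating
#' point: ~6 nm FWHM probe, 1.5e6 electrons/s, 2.5 ms dwell, 20 nm step
#' (≈ 3750 electrons and ~1 e⁻/Å² per scan position).
#'
#' @param fwhm_nm probe full width at half maximum, nm.
#' @param electron_rate electrons per second in the probe.
#' @param dwell_s dwell time per scan position, seconds.
#' @param step_nm scan step size, nm.
#' @return object of class `probe_model`.
#' @export
probe_model <- function(fwhm_nm = 6, electron_rate = 1.5e6,
                        dwell_s = 0.0025, step_nm = 20) {
  stopifnot(fwhm_nm > 0, electron_rate > 0, dwell_s >= 0, step_nm > 0)
  structure(list(fwhm_nm = fwhm_nm, electron_rate = electron_rate,
                 dwell_s = dwell_s, step_nm = step_nm),
            class = "probe_model")
}

#' @export
print.probe_model <- function(x, ...) {
  cat(sprintf("probe: %.1f nm FWHM, %.3g e-/s, %.4g s dwell, %.0f nm step (%.0f e-/step)\n",
              x$fwhm_nm, x$electron_rate, x$dwell_s, x$step_nm,
              x$electron_rate * x$dwell_s))
  invisible(x)
}

#' Geometric centre of the detector frame
#' @param detector a [detector_model()].
#' @return numeric (row, col) centre, 1-based pixel coordinates.
#' @export
detector_centre <- function(detector) {
  c((detector$n_ky + 1) / 2, (detector$n_kx + 1) / 2)
}

# strip index of each detector column
strip_of_column <- function(detector) {
  ((seq_len(detector$n_kx) - 1L) %/% detector$strip_width) + 1L
}
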