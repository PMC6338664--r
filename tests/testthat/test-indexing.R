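# Peak enumeration, intensity extraction, RMSD template matching.

test_that("peak enumeration matches a brute-force Miller loop", {
  det <- detector_model()
  cell <- unit_cell(5, 10, 30)
  pk <- enumerate_peaks(cell, det, tilt_range = 1, max_resolution = 2)
  expect_gt(nrow(pk), 0)

  # independent oracle: plain loop over h,k,l with the textbook excitation
  # error, the same reachability bound, and direct projection
  lam <- 0.0196875
  ctr <- c((det$n_ky + 1) / 2, (det$n_kx + 1) / 2)
  B <- cell$reciprocal
  found <- NULL
  for (h in -3:3) for (k in -6:6) for (l in -16:16) {
    if (h == 0 && k == 0 && l == 0) next
    g <- as.vector(B %*% c(h, k, l))
    if (sum(g^2) > (1 / 2)^2) next
    # reachability symmetrised over the Friedel pair, as in the peak set
    s0 <- min(abs(-g[3] - lam * sum(g^2) / 2),
              abs(+g[3] - lam * sum(g^2) / 2))
    reach <- max(0, s0 - sqrt(sum(g^2)) * sin(pi / 180))
    if (reach >= 4 * (1 / 100)) next
    py <- round(ctr[1] + det$px_per_invA * g[2])
    px <- round(ctr[2] + det$px_per_invA * g[1])
    if (py < 1 || py > det$n_ky || px < 1 || px > det$n_kx) next
    if ((py - ctr[1])^2 + (px - ctr[2])^2 <= (2 * det$beam_radius_px)^2) next
    found <- rbind(found, c(py, px))
  }
  found <- found[!duplicated(found), , drop = FALSE]
  expect_setequal(paste(pk[, 1], pk[, 2]), paste(found[, 1], found[, 2]))

  # Friedel mates are both present at zero mean orientation: the peak set
  # is symmetric under inversion through the frame centre, up to the 1 px
  # ambiguity of placing half-integer positions on an even pixel grid
  my <- det$n_ky + 1 - pk[, 1]; mx <- det$n_kx + 1 - pk[, 2]
  has_mate <- vapply(seq_len(nrow(pk)), function(i)
    any(abs(pk[, 1] - my[i]) <= 1 & abs(pk[, 2] - mx[i]) <= 1), logical(1))
  expect_true(all(has_mate))
})

test_that("an exclusion radius beyond the detector leaves no peaks", {
  det <- small_detector()
  expect_error(enumerate_peaks(peptide_cell(), det,
                               exclusion_radius = 100), "empty peak set")
})

test_that("intensity extraction integrates, scales and tie-breaks", {
  shape <- c(64L, 64L)
  peaks <- structure(cbind(k_y = c(10L, 30L, 50L), k_x = c(10L, 30L, 50L)),
                     integration_radius = 4, class = "peak_set")
  M <- matrix(0, 64, 64)
  M[10, 10] <- 40; M[31, 30] <- 15; M[29, 30] <- 5; M[50, 52] <- 10
  v <- extract_scaled_intensities(M, peaks)
  expect_equal(v, c(1, 0.5, 0.25))
  # single nonzero peak
  M2 <- matrix(0, 64, 64); M2[30, 30] <- 7
  expect_equal(extract_scaled_intensities(M2, peaks), c(0, 1, 0))
  # all-zero -> flagged
  v0 <- extract_scaled_intensities(matrix(0, 64, 64), peaks)
  expect_true(isTRUE(attr(v0, "flagged")))
  # overlapping discs: the pixel goes to the nearer peak
  peaks2 <- structure(cbind(k_y = c(20L, 26L), k_x = c(20L, 20L)),
                      integration_radius = 4, class = "peak_set")
  M3 <- matrix(0, 64, 64); M3[23, 20] <- 8; M3[24, 20] <- 6
  expect_equal(extract_scaled_intensities(M3, peaks2), c(1, 0.75))
})

test_that("RMSD matching reproduces the hand-worked oracle", {
  peaks <- structure(cbind(k_y = c(5L, 10L, 15L), k_x = c(5L, 10L, 15L)),
                     integration_radius = 4, class = "peak_set")
  lib <- structure(list(
    entries = data.frame(tilt_x = c(0, 1), tilt_y = c(0, 0),
                         thickness = c(100, 100)),
    intensities = rbind(c(1.0, 0.4, 0.25), c(0.2, 1.0, 0.9)),
    peaks = peaks), class = "template_library")
  r <- rmsd_match(c(1.0, 0.5, 0.25), lib)
  expect_equal(r$rmsd, sqrt(0.01 / 3), tolerance = 1e-12)
  expect_equal(r$index, 1L)
})

test_that("every library entry matches itself with RMSD zero", {
  det <- small_detector()
  cell <- peptide_cell()
  pk <- enumerate_peaks(cell, det, tilt_range = 1.25)
  lib <- build_template_library(cell, det, pk, tilt_range = 1,
                                tilt_step = 0.25, thicknesses = c(100, 300))
  rmsds <- vapply(seq_len(nrow(lib$entries)), function(i)
    rmsd_match(lib$intensities[i, ], lib)$rmsd, numeric(1))
  expect_true(all(rmsds == 0))
  idx <- vapply(seq_len(nrow(lib$entries)), function(i)
    rmsd_match(lib$intensities[i, ], lib)$index, integer(1))
  expect_equal(idx, seq_len(nrow(lib$entries)))
})

test_that("RMSD is invariant to a common positive scaling of the pattern", {
  det <- small_detector()
  cell <- peptide_cell()
  pk <- enumerate_peaks(cell, det, tilt_range = 1.25)
  lib <- build_template_library(cell, det, pk, tilt_range = 1,
                                tilt_step = 0.25, thicknesses = c(200))
  f <- kinematic_pattern(cell, c(0.5, -0.25), 200, det)
  r1 <- rmsd_match(f, lib)
  r2 <- rmsd_match(f * 37.5, lib)
  expect_equal(r1$index, r2$index)
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-10)
})

test_that("a noisy pattern is assigned within one 0.25-degree grid step", {
  det <- detector_model()
  cell <- peptide_cell()
  prb <- probe_model()
  pk <- enumerate_peaks(cell, det, tilt_range = 1.5)
  lib <- build_template_library(cell, det, pk, tilt_range = 1.5,
                                tilt_step = 0.25,
                                thicknesses = c(100, 300))
  truth <- c(1.0, -0.5)
  avg <- counted_average(truth, 300, det, prb, seed = 71)
  r <- rmsd_match(avg, lib)
  expect_false(r$unindexable)
  expect_lte(abs(r$tilt_x - truth[1]), 0.25)
  expect_lte(abs(r$tilt_y - truth[2]), 0.25)
})

test_that("orientation maps render deviations and unindexable clusters", {
  res <- structure(list(
    per_cluster = data.frame(
      tilt_x = c(1, 1, NA), tilt_y = c(-1, -1, NA),
      thickness = c(100, 100, NA), rmsd = c(0.1, 0.1, NA),
      rmsd_runner_up = NA, unindexable = c(FALSE, FALSE, TRUE),
      delta_x = c(0, 0, NA), delta_y = c(0, 0, NA)),
    mean_orientation = c(1, -1)), class = "orientation_result")
  lm <- matrix(c(1, 2, 3, 1), 2, 2)
  m <- orientation_map(res, lm)
  # identical orientations -> zero deviation, uniform (white) colour
  expect_true(all(m$delta_x[lm != 3] == 0))
  expect_true(all(m$rgb[1, 1, ] == 1))
  # unindexable -> reserved neutral grey
  expect_true(all(m$rgb[1, 2, ] == 0.5))
  expect_true(is.na(m$delta_x[1, 2]))
})

test_that("the scan mean orientation weights clusters by match quality", {
  means <- list(a = 1, b = 2)  # placeholders; intensities supplied directly
  peaks <- structure(cbind(k_y = c(5L, 10L), k_x = c(5L, 10L)),
                     integration_radius = 4, class = "peak_set")
  lib <- structure(list(
    entries = data.frame(tilt_x = c(-1, 1), tilt_y = c(0, 0),
                         thickness = c(100, 100)),
    intensities = rbind(c(1, 0), c(0, 1)),
    peaks = peaks), class = "template_library")
  M1 <- matrix(0, 20, 20); M1[5, 5] <- 10            # exact entry 1
  M2 <- matrix(0, 20, 20); M2[10, 10] <- 10; M2[5, 5] <- 3  # near entry 2
  res <- index_clusters(list(M1, M2), lib)
  expect_equal(res$per_cluster$tilt_x, c(-1, 1))
  # the perfect match (rmsd 0) dominates the weighted mean
  expect_lt(res$mean_orientation[1], 0)
})
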