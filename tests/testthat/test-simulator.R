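# Kinematic engine and detector rendering.

test_that("patterns are deterministic, non-negative, centre-dominated", {
  det <- small_detector()
  cell <- peptide_cell()
  f1 <- kinematic_pattern(cell, c(0, 0), 300, det)
  f2 <- kinematic_pattern(cell, c(0, 0), 300, det)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0))
  expect_equal(sum(f1), exp(-300 / 332), tolerance = 1e-12)
  # the (000) disc is the unique global maximum
  ctr <- detector_centre(det)
  mx <- which(f1 == max(f1), arr.ind = TRUE)
  expect_true(all(sqrt((mx[, 1] - ctr[1])^2 + (mx[, 2] - ctr[2])^2) <=
                    det$beam_radius_px))
})

test_that("tilting changes the excited set and moves Friedel mates in opposite senses", {
  det <- detector_model()
  cell <- peptide_cell()
  p0 <- kinematic_pattern(cell, c(0, 0), 200, det, as_points = TRUE)
  p1 <- kinematic_pattern(cell, c(1, 0), 200, det, as_points = TRUE)
  k0 <- apply(p0$hkl, 1, paste, collapse = ",")
  k1 <- apply(p1$hkl, 1, paste, collapse = ",")
  expect_false(setequal(k0, k1))

  # brute-force oracle from the reciprocal basis:
  # s(g) = -g_z - lambda |g|^2 / 2, so s(g) + s(-g) = -lambda |g|^2 is
  # tilt-invariant and the tilt-induced displacements of a Friedel pair
  # are exactly opposite: delta_s(-g) = -delta_s(g)
  lam <- 0.0196875
  s_of <- function(hkl, tilt_x) {
    g <- nbed4d:::rot_x(tilt_x) %*% (cell$reciprocal %*% hkl)
    -g[3] - lam * sum(g^2) / 2
  }
  w_of <- function(hkl, tilt_x) {
    g <- cell$reciprocal %*% hkl
    sig <- sqrt((1 / 2000)^2 + (sqrt(sum(g^2)) * sin(0.2 * pi / 180))^2)
    exp(-s_of(hkl, tilt_x)^2 / (2 * sig^2))
  }
  flips <- 0L
  for (i in seq_len(nrow(p0$hkl))) {
    hkl <- as.numeric(p0$hkl[i, ])
    ds_plus <- s_of(hkl, 1) - s_of(hkl, 0)
    ds_minus <- s_of(-hkl, 1) - s_of(-hkl, 0)
    expect_equal(ds_minus, -ds_plus, tolerance = 1e-10)
    dplus <- w_of(hkl, 1) - w_of(hkl, 0)
    dminus <- w_of(-hkl, 1) - w_of(-hkl, 0)
    if (abs(dplus) > 1e-4 && abs(dminus) > 1e-4 &&
        sign(dplus) != sign(dminus)) flips <- flips + 1L
  }
  # pairs straddling the Ewald sphere brighten on one side and dim on the
  # other
  expect_gt(flips, 0)
})

test_that("zero tilt gives Friedel-symmetric intensities for a centrosymmetric projection", {
  det <- detector_model()
  cell <- unit_cell(5, 10, 30)  # orthorhombic: centrosymmetric projection
  pts <- kinematic_pattern(cell, c(0, 0), 150, det, as_points = TRUE)
  expect_gt(nrow(pts$hkl), 0)
  key <- apply(pts$hkl, 1, paste, collapse = ",")
  mate <- apply(-pts$hkl, 1, paste, collapse = ",")
  expect_true(all(mate %in% key))
  expect_equal(pts$intensity[match(mate, key)], pts$intensity,
               tolerance = 1e-8)
})

test_that("degenerate cells and empty detectors are reported", {
  expect_error(kinematic_pattern(list(a = 1), c(0, 0), 100), "unit_cell")
  # camera length so long that every reflection lands off the detector
  det <- detector_model(n_ky = 32L, n_kx = 32L, px_per_invA = 5000,
                        beam_radius_px = 2)
  expect_warning(kinematic_pattern(peptide_cell(), c(0, 0), 100, det),
                 "empty pattern")
})

test_that("rendering is seeded, additive in offsets, and conserves electrons", {
  det <- small_detector()
  prb <- probe_model()
  zero <- matrix(0, det$n_ky, det$n_kx)
  expect_error(render_detector(zero, prb, det), "seed")
  expect_error(render_detector(zero - 1, prb, det, seed = 1), "non-negative")

  f1 <- render_detector(zero, prb, det, seed = 9)
  f2 <- render_detector(zero, prb, det, seed = 9)
  expect_identical(f1, f2)
  # an all-zero expected frame contains only strip offsets + read noise
  strip_id <- nbed4d:::strip_of_column(det)
  for (s in unique(strip_id)) {
    expect_equal(mean(f1[, strip_id == s]), det$strip_offsets[s],
                 tolerance = 0.1)
  }

  # electron conservation: mean deposited electrons -> rate * dwell
  expected <- kinematic_pattern(peptide_cell(), c(0, 0), 0, det)
  n_rep <- 25
  totals <- vapply(seq_len(n_rep), function(i) {
    sum(attr(render_detector(expected, prb, det, seed = 100 + i,
                             return_electrons = TRUE), "electrons"))
  }, numeric(1))
  n_e <- prb$electron_rate * prb$dwell_s
  expect_lt(abs(mean(totals) - n_e), 3 * sqrt(n_e / n_rep))
})

test_that("point-spread blur conserves interior signal", {
  M <- matrix(0, 32, 32); M[16, 16] <- 100; M[10, 22] <- 50
  B <- nbed4d:::gaussian_blur(M, 1.5)
  expect_equal(sum(B), sum(M), tolerance = 1e-6)
  expect_lt(max(B), max(M))
})

test_that("scans over vacuum and thickness ramps behave physically", {
  det <- small_detector()
  prb <- probe_model()
  # 2x2 pure vacuum: frames are central-beam-only and statistically alike
  z <- matrix(0, 2, 2)
  ph <- crystal_phantom(matrix("vacuum", 2, 2), z, z, z)
  expect_error(generate_scan(ph, prb, det), "seed")
  scan <- generate_scan(ph, prb, det, seed = 4)
  expect_equal(dim(scan$data), c(2, 2, det$n_ky, det$n_kx))
  n_e <- prb$electron_rate * prb$dwell_s
  expect_true(all(abs(scan$truth$electrons - n_e) < 4 * sqrt(n_e)))

  # thickness ramp: the noise-free central-beam integral decreases
  # monotonically with thickness (exponential attenuation law)
  ramp <- seq(0, 500, length.out = 6)
  ph2 <- phantom_bands(2, 6, rbind(c(0, 0)), thickness = ramp[-1],
                       vacuum_cols = 1)
  nf <- generate_scan(ph2, prb, det, noise = FALSE)
  ctr <- detector_centre(det)
  integ <- vapply(1:6, function(ix)
    integrate_transmission(nf$data[1, ix, , ], ctr, det$beam_radius_px),
    numeric(1))
  expect_true(all(diff(integ) < 0))
  # and matches the attenuation law exactly in the noise-free limit
  expect_equal(integ[1], n_e, tolerance = 1e-6)
})

test_that("same seed reproduces a whole scan bit for bit", {
  det <- small_detector()
  ph <- phantom_bands(3, 3, rbind(c(0.5, -0.5)), thickness = 200,
                      vacuum_cols = 1)
  s1 <- generate_scan(ph, probe_model(), det, seed = 21)
  s2 <- generate_scan(ph, probe_model(), det, seed = 21)
  expect_identical(s1$data, s2$data)
})
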