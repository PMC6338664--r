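#' Triclinic unit cell
#'
#' Construct a unit cell from lengths (ångström) and angles (degrees).
#' The cell carries its direct and reciprocal basis matrices; the
#' reciprocal basis (crystallographic convention, no factor of 2*pi) is
#' what the kinematic diffraction engine works from.
#'
#' @param a,b,c cell edge lengths in ångström; must be positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `basis` (3x3 direct basis, columns are the
#'   cell vectors in a cartesian frame), `reciprocal` (3x3 reciprocal
#'   basis, columns are a*, b*, c*) and `volume` (ų).
#' @examples
#' cell <- unit_cell(4.94, 10.34, 31.15, 94.21, 92.36, 102.2)
#' cell$volume
#' d_spacing(cell, c(0, 0, 1))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("invalid cell: lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees")
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(v2) || v2 <= 0)
    stop("invalid cell: degenerate (non-invertible) basis")
  v <- sqrt(v2)
  # standard cartesian frame: a along x, b in the xy plane
  basis <- cbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * v / sg)
  )
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         basis = basis,
         reciprocal = solve(t(basis)),
         volume = a * b * c * v),
    class = "unit_cell")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f A, alpha=%.2f beta=%.2f gamma=%.2f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("volume: %.1f A^3\n", x$volume))
  invisible(x)
}

#' Prion peptide (QYNNQNNFV) crystal cell
#'
#' The triclinic unit cell of the QYNNQNNFV prion-peptide nanocrystals:
#' a=4.94, b=10.34, c=31.15 Å, alpha=94.21, beta=92.36, gamma=102.2 deg.
#' Used as the default phantom cell throughout the package.
#' @return A [unit_cell()].
#' @export
peptide_cell <- function() {
  unit_cell(4.94, 10.34, 31.15, 94.21, 92.36, 102.2)
}

#' Interplanar spacings
#'
#' d-spacing of one or more reflections, d = 1/|g(hkl)|.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer vector of length 3, or a matrix with three columns.
#' @return numeric vector of d-spacings in ångström.
#' @export
d_spacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  g <- cell$reciprocal %*% t(hkl)
  1 / sqrt(colSums(g^2))
}

#' Reciprocal-lattice vectors for a block of Miller indices
#'
#' Enumerates all reflections with |g| <= 1/max_resolution, excluding (000).
#' @param cell a [unit_cell()].
#' @param max_resolution resolution cutoff in ångström (> 0).
#' @return list with `hkl` (n x 3 integer matrix) and `g` (3 x n matrix of
#'   reciprocal vectors, Å⁻¹) in the crystal's cartesian frame.
#' @keywords internal
enumerate_reflections <- function(cell, max_resolution) {
  stopifnot(max_resolution > 0)
  gmax <- 1 / max_resolution
  # |a*| >= 1/a etc., so |h| <= gmax * a bounds the index range
  hmax <- ceiling(gmax * c(cell$a, cell$b, cell$c)) + 1L
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                               k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  keep <- rowSums(abs(hkl)) > 0
  hkl <- hkl[keep, , drop = FALSE]
  g <- cell$reciprocal %*% t(hkl)
  inside <- colSums(g^2) <= gmax^2
  list(hkl = hkl[inside, , drop = FALSE], g = g[, inside, drop = FALSE])
}

# rotation matrices about the detector x (k_x, horizontal) and y axes;
# angles in degrees
rot_x <- function(deg) {
  c1 <- cospi(deg / 180); s1 <- sinpi(deg / 180)
  matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
}
rot_y <- function(deg) {
  c1 <- cospi(deg / 180); s1 <- sinpi(deg / 180)
  matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
}
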