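#' Crystal phantom for synthetic scans
#'
#' Ground-truth description of the specimen on the scan grid: a support
#' label per position (vacuum / carbon / crystal), and per-position lattice
#' tilt (degrees) and thickness (nm) wherever there is material. The
#' phantom is what the simulator renders and what parameter-recovery tests
#' compare against.
#'
#' @param labels character matrix (scan_y x scan_x) with entries
#'   "vacuum", "carbon" or "crystal".
#' @param tilt_x,tilt_y numeric matrices of lattice tilt in degrees, same
#'   shape as `labels`; ignored (taken as 0) off-crystal.
#' @param thickness numeric matrix of specimen thickness in nm; must be 0
#'   on vacuum and >= 0 everywhere.
#' @param cell the [unit_cell()] of the crystal.
#' @param domains optional integer matrix of ground-truth domain ids
#'   (0 = not crystal), used by clustering-recovery tests.
#' @return object of class `crystal_phantom`.
#' @export
crystal_phantom <- function(labels, tilt_x, tilt_y, thickness,
                            cell = peptide_cell(), domains = NULL) {
  stopifnot(is.matrix(labels))
  dm <- dim(labels)
  ok <- function(m) is.matrix(m) && all(dim(m) == dm)
  if (!ok(tilt_x) || !ok(tilt_y) || !ok(thickness))
    stop("phantom fields must all share the scan-grid dimensions")
  if (!all(labels %in% c("vacuum", "carbon", "crystal")))
    stop("labels must be 'vacuum', 'carbon' or 'crystal'")
  if (any(thickness < 0)) stop("thickness must be non-negative")
  if (any(thickness[labels == "vacuum"] != 0))
    stop("vacuum positions must have thickness 0")
  if (is.null(domains)) {
    domains <- matrix(0L, dm[1], dm[2])
    domains[labels == "crystal"] <- 1L
  }
  structure(list(labels = labels, tilt_x = tilt_x, tilt_y = tilt_y,
                 thickness = thickness, cell = cell,
                 domains = domains, dim = dm),
            class = "crystal_phantom")
}

#' @export
print.crystal_phantom <- function(x, ...) {
  tb <- table(factor(x$labels, c("vacuum", "carbon", "crystal")))
  cat(sprintf("crystal phantom: %d x %d scan (%d vacuum, %d carbon, %d crystal), %d domain(s)\n",
              x$dim[1], x$dim[2], tb[1], tb[2], tb[3],
              length(setdiff(unique(as.vector(x$domains)), 0L))))
  invisible(x)
}

#' Banded mosaic phantom
#'
#' Convenience phantom builder: a vacuum margin on the left (over a hole),
#' an optional carbon strip, and the remaining columns filled by a needle
#' crystal split into vertical tilt domains — the simplest emulation of the
#' mosaic sub-domain structure seen in peptide nanocrystals.
#'
#' @param n_y,n_x scan grid size.
#' @param domain_tilts k x 2 matrix; row i is the (tilt_x, tilt_y) of
#'   domain i in degrees.
#' @param thickness scalar thickness (nm), or a vector over the crystal
#'   columns (a ramp), or a full matrix.
#' @param vacuum_cols,carbon_cols number of leading columns of vacuum and
#'   of carbon support.
#' @param carbon_thickness nm of amorphous support under the carbon label.
#' @param cell crystal [unit_cell()].
#' @return a [crystal_phantom()].
#' @export
phantom_bands <- function(n_y = 12, n_x = 12,
                          domain_tilts = rbind(c(0, 0)),
                          thickness = 300,
                          vacuum_cols = 2, carbon_cols = 0,
                          carbon_thickness = 30,
                          cell = peptide_cell()) {
  domain_tilts <- rbind(domain_tilts)
  k <- nrow(domain_tilts)
  first_xtal <- vacuum_cols + carbon_cols + 1L
  if (first_xtal > n_x) stop("no crystal columns left")
  xtal_cols <- first_xtal:n_x
  if (length(xtal_cols) < k) stop("fewer crystal columns than domains")

  labels <- matrix("crystal", n_y, n_x)
  if (vacuum_cols > 0) labels[, seq_len(vacuum_cols)] <- "vacuum"
  if (carbon_cols > 0) labels[, vacuum_cols + seq_len(carbon_cols)] <- "carbon"

  tilt_x <- matrix(0, n_y, n_x); tilt_y <- matrix(0, n_y, n_x)
  domains <- matrix(0L, n_y, n_x)
  band <- if (k == 1L) rep(1L, length(xtal_cols))
          else cut(seq_along(xtal_cols), k, labels = FALSE)
  for (i in seq_len(k)) {
    cols <- xtal_cols[band == i]
    tilt_x[, cols] <- domain_tilts[i, 1]
    tilt_y[, cols] <- domain_tilts[i, 2]
    domains[, cols] <- i
  }

  th <- matrix(0, n_y, n_x)
  if (is.matrix(thickness)) {
    th <- thickness
  } else if (length(thickness) == 1L) {
    th[, xtal_cols] <- thickness
  } else {
    th[, xtal_cols] <- matrix(rep(rep_len(thickness, length(xtal_cols)),
                                  each = n_y), n_y)
  }
  if (carbon_cols > 0) th[labels == "carbon"] <- carbon_thickness
  th[labels == "vacuum"] <- 0

  crystal_phantom(labels, tilt_x, tilt_y, th, cell = cell, domains = domains)
}
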