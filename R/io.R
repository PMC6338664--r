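# Containers, configuration and the pipeline driver.
#
# Scans and stage artefacts are stored as single-object RDS containers
# with a format tag and schema validation on load; sparse scans also
# round-trip through a plain-text export (one line per nonzero pixel) for
# interoperability. A YAML-serialisable config drives the full synthetic
# pipeline: simulate -> count -> shift-correct -> thickness -> cluster ->
# index; every stage writes an independent, resumable artefact stamped
# with the config hash.

FORMAT_VERSION <- "nbed4d-1"

#' Save a scan or stage artefact
#' @param x a `scan4d`, `sparse_scan` or other pipeline object.
#' @param path output file path.
#' @export
save_scan <- function(x, path) {
  saveRDS(list(format = FORMAT_VERSION, class = class(x)[1], object = x),
          path)
  invisible(path)
}

#' Load a scan container
#'
#' Auto-detects dense (`scan4d`) vs sparse (`sparse_scan`) containers and
#' validates the schema; malformed or truncated files give a descriptive
#' error naming what is missing rather than a crash.
#'
#' @param path file written by [save_scan()].
#' @return the stored object.
#' @export
load_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("malformed container (",
                                           conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, FORMAT_VERSION))
    stop("schema error: missing or wrong 'format' tag")
  x <- obj$object
  if (identical(obj$class, "scan4d")) {
    for (f in c("data", "meta"))
      if (is.null(x[[f]])) stop("schema error: scan4d missing field '", f, "'")
    if (length(dim(x$data)) != 4) stop("schema error: /data must be 4-D")
  } else if (identical(obj$class, "sparse_scan")) {
    for (f in c("frames", "shape", "frame_shape", "meta"))
      if (is.null(x[[f]])) stop("schema error: sparse_scan missing field '", f, "'")
  }
  x
}

#' Export a sparse scan to plain text
#'
#' One line per nonzero pixel: `scan_y scan_x k_y k_x count`, 1-based
#' indices, after a `#`-prefixed header describing shapes.
#'
#' @param sp a `sparse_scan`.
#' @param path output text file.
#' @export
write_sparse_text <- function(sp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nbed4d sparse scan: scan %d x %d, frame %d x %d, 1-based indices",
                     sp$shape[1], sp$shape[2],
                     sp$frame_shape[1], sp$frame_shape[2]), con)
  writeLines("scan_y scan_x k_y k_x count", con)
  for (ix in seq_len(sp$shape[2])) for (iy in seq_len(sp$shape[1])) {
    p <- sparse_frame(sp, iy, ix)
    if (nrow(p))
      writeLines(sprintf("%d %d %d %d %d", iy, ix, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text sparse scan export
#' @param path file written by [write_sparse_text()].
#' @return a `sparse_scan` (without metadata beyond shapes).
#' @export
read_sparse_text <- function(path) {
  hdr <- readLines(path, n = 1)
  nums <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  if (length(nums) < 5) stop("schema error: bad sparse text header")
  shape <- nums[2:3]; frame_shape <- nums[4:5]
  tab <- utils::read.table(path, skip = 1, header = TRUE)
  frames <- vector("list", prod(shape))
  for (k in seq_along(frames)) {
    iy <- ((k - 1L) %% shape[1]) + 1L
    ix <- ((k - 1L) %/% shape[1]) + 1L
    sel <- tab$scan_y == iy & tab$scan_x == ix
    m <- cbind(k_y = tab$k_y[sel], k_x = tab$k_x[sel],
               count = tab$count[sel])
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    frames[[k]] <- structure(m, frame_shape = frame_shape,
                             class = "sparse_pattern")
  }
  totals <- matrix(vapply(frames, function(p) sum(p[, 3]), numeric(1)),
                   shape[1], shape[2])
  structure(list(frames = frames, shape = shape, frame_shape = frame_shape,
                 totals = totals, background = NULL,
                 meta = list(), truth = NULL),
            class = "sparse_scan")
}

#' Pipeline configuration
#'
#' All stage parameters, with the experimental operating point as
#' defaults, in a YAML-round-trippable list. Every randomised stage draws
#' from the single `seed`.
#'
#' @param seed master seed (required).
#' @param scan_ny,scan_nx synthetic scan grid.
#' @param domain_tilts k x 2 matrix of domain tilts (degrees).
#' @param thickness crystal thickness, nm (scalar or ramp vector).
#' @param vacuum_cols leading vacuum columns of the phantom.
#' @param lambda_mfp mean free path, nm.
#' @param bin_factor,mask_radius clustering preprocessing.
#' @param K number of clusters, or "auto" for G-means.
#' @param tilt_range,tilt_step,thicknesses template-library axes.
#' @param max_rounds shift-correction rounds.
#' @param detector,probe model objects (defaults used if NULL).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            scan_ny = 12, scan_nx = 12,
                            domain_tilts = rbind(c(0.5, -0.5), c(-0.5, 0.5)),
                            thickness = 300, vacuum_cols = 2,
                            lambda_mfp = 332,
                            bin_factor = 8, mask_radius = 3,
                            K = "auto",
                            tilt_range = 1, tilt_step = 0.25,
                            thicknesses = c(100, 300),
                            max_rounds = 3,
                            detector = NULL, probe = NULL) {
  if (missing(seed)) stop("config validation error: seed is required")
  cfg <- list(seed = as.integer(seed), scan_ny = scan_ny, scan_nx = scan_nx,
              domain_tilts = rbind(domain_tilts), thickness = thickness,
              vacuum_cols = vacuum_cols, lambda_mfp = lambda_mfp,
              bin_factor = bin_factor, mask_radius = mask_radius, K = K,
              tilt_range = tilt_range, tilt_step = tilt_step,
              thicknesses = thicknesses, max_rounds = max_rounds,
              detector = if (is.null(detector)) detector_model() else detector,
              probe = if (is.null(probe)) probe_model() else probe)
  if (is.null(cfg$lambda_mfp) || cfg$lambda_mfp <= 0)
    stop("config validation error: lambda_mfp must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialise / restore a pipeline config as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  plain$detector <- unclass(plain$detector)
  plain$probe <- unclass(plain$probe)
  plain$domain_tilts <- apply(plain$domain_tilts, 1, as.numeric,
                              simplify = FALSE)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  plain <- yaml::read_yaml(path)
  det <- do.call(detector_model, plain$detector[
    setdiff(names(plain$detector), character(0))])
  prb <- do.call(probe_model, plain$probe)
  plain$detector <- NULL; plain$probe <- NULL
  plain$domain_tilts <- do.call(rbind, plain$domain_tilts)
  do.call(pipeline_config, c(plain, list(detector = det, probe = prb)))
}

# md5 of the serialised config: the provenance stamp on every artefact
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  wc <- tempfile()
  on.exit(unlink(wc), add = TRUE)
  writeLines(yaml::as.yaml(rapply(unclass(config), unclass, how = "replace")), wc)
  unname(tools::md5sum(wc))
}

#' Run the full synthetic pipeline
#'
#' simulate -> background/count -> shift-correct -> thickness -> cluster
#' -> build library -> index. Each stage logs its parameters and (when
#' `out_dir` is given) writes an independent artefact stamped with the
#' config hash; identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for stage artefacts.
#' @param verbose print stage progress.
#' @return list of stage artefacts: `scan`, `background`, `sparse`,
#'   `shifts`, `thickness`, `clusters`, `spatial`, `library`,
#'   `orientations`, `map`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      attr(x, "config_hash") <- hash
      save_scan(x, file.path(out_dir, paste0(name, ".rds")))
    }
    x
  }
  stage <- function(name, expr) {
    say("[%s] ...", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  det <- config$detector; prb <- config$probe
  phantom <- stage("simulate", phantom_bands(
    config$scan_ny, config$scan_nx, config$domain_tilts,
    thickness = config$thickness, vacuum_cols = config$vacuum_cols))
  scan <- emit(stage("simulate", generate_scan(
    phantom, prb, det, seed = config$seed,
    lambda_mfp = config$lambda_mfp)), "scan")

  bg <- stage("count", estimate_background(scan))
  sparse <- emit(stage("count", sparsify_scan(scan, bg)), "sparse")

  shifted <- stage("correct-shift", correct_shifts(
    sparse, beam_radius = det$beam_radius_px, max_rounds = config$max_rounds))
  sparse <- emit(shifted$scan, "shifted")

  vac <- phantom$labels == "vacuum"
  th <- stage("thickness", {
    I0 <- estimate_I0(sparse, vac, beam_radius = det$beam_radius_px)
    peaks0 <- find_bragg_peaks(sparse, beam_radius = det$beam_radius_px)
    thickness_map(sparse, lambda_mfp = config$lambda_mfp, I0 = I0,
                  beam_radius = det$beam_radius_px,
                  bragg_positions = peaks0, vacuum_mask = vac)
  })
  th <- emit(th, "thickness")

  feats <- stage("cluster", preprocess_patterns(
    sparse, config$bin_factor, config$mask_radius))
  model <- stage("cluster", {
    if (identical(config$K, "auto")) {
      gmeans_select_K(feats, seed = config$seed)$model
    } else kmeans_cluster(feats, as.integer(config$K),
                          seed = config$seed, nstart = 3)
  })
  spatial <- emit(stage("cluster", cluster_spatial_map(model, sparse)),
                  "clusters")

  peaks <- stage("build-library", enumerate_peaks(
    phantom$cell, det, tilt_range = config$tilt_range))
  library <- stage("build-library", build_template_library(
    phantom$cell, det, peaks, tilt_range = config$tilt_range,
    tilt_step = config$tilt_step, thicknesses = config$thicknesses))

  orient <- emit(stage("index", index_clusters(spatial$means, library)),
                 "orientations")
  map <- stage("index", orientation_map(orient, spatial$label_map))

  say("pipeline complete (config %s)", hash)
  list(scan = scan, background = bg, sparse = sparse,
       shifts = shifted$shifts, thickness = th, clusters = model,
       spatial = spatial, library = library, orientations = orient,
       map = map, config_hash = hash)
}
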