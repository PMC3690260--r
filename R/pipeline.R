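#' End-to-end motion-compensation pipeline
#'
#' Runs simulate (optional) -> track -> triangulate -> extract/smooth signal
#' -> reconstruct (uncompensated and compensated) -> evaluate, writing every
#' stage product plus a manifest to the output directory. All randomness
#' flows from the single configured seed.
#'
#' @param config Either a path to a YAML file or a list with (subsets of)
#'   the entries understood by [pipeline_config()].
#' @return The manifest (invisibly written to `manifest.json`): per-stage
#'   output paths, the seed, configuration echo and file checksums of the
#'   deterministic stage outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cbctmoco")),
                   seed = cfg$seed, config = cfg[setdiff(names(cfg), "phantom")],
                   outputs = list())
  t_all <- proc.time()[3]

  geom <- do.call(circular_trajectory, cfg$geometry)
  write_geometry(geom, file.path(cfg$out_dir, "geometry.json"))
  manifest$outputs$geometry <- "geometry.json"

  spec <- cfg$phantom
  stack <- forward_project(spec, geom, noise = cfg$noise,
                           fluence = cfg$fluence,
                           seed = if (cfg$noise == "poisson") cfg$seed else NULL)
  write_projections(stack, file.path(cfg$out_dir, "projections.mhd"))
  manifest$outputs$projections <- "projections.mhd"

  if (cfg$tracking_enabled) {
    if (is.null(cfg$seed_point))
      stop("tracking is enabled but no seed point is configured")
    track <- track_sequence(stack, cfg$seed_point, cfg$tracking,
                            rng_seed = cfg$seed)
    vertices <- cbind(track$u_vertex, track$v_vertex)
    write_track(track, file.path(cfg$out_dir, "track.csv"))
    manifest$outputs$track <- "track.csv"
  } else {
    # perfect tracking: exact projections of the moving diaphragm top
    truth <- diaphragm_top_truth(spec, geom$timestamps)
    vertices <- t(vapply(seq_len(geom$n_views), function(i)
      project_point(geom$matrices[[i]], truth[i, ]), numeric(2)))
  }

  pts <- triangulate_sequence(vertices, geom, offset_deg = cfg$offset_deg,
                              mode = cfg$triangulation_mode)
  write_points3d(pts, file.path(cfg$out_dir, "points3d.csv"))
  manifest$outputs$points3d <- "points3d.csv"

  sig <- extract_signal(pts, ref_index = cfg$ref_index,
                        timestamps = geom$timestamps)
  sig_s <- smooth_signal(sig, cfg$signal_sigma)
  write_signal(sig, file.path(cfg$out_dir, "signal.csv"), smoothed = sig_s)
  manifest$outputs$signal <- "signal.csv"

  grid <- make_grid(cfg$grid_n, cfg$grid_spacing, cfg$grid_center)
  filt <- filter_projections(stack, geom)
  vol_unc <- backproject(filt, geom, motion = NULL, grid = grid)
  vol_cmp <- backproject(filt, geom,
                         motion = constant_motion_model(sig_s), grid = grid)
  write_volume(vol_unc, file.path(cfg$out_dir, "uncompensated.mhd"))
  write_volume(vol_cmp, file.path(cfg$out_dir, "compensated.mhd"))
  manifest$outputs$uncompensated <- "uncompensated.mhd"
  manifest$outputs$compensated <- "compensated.mhd"

  manifest$elapsed_s <- as.numeric(proc.time()[3] - t_all)
  manifest$checksums <- as.list(tools::md5sum(
    file.path(cfg$out_dir, c("track.csv", "points3d.csv", "signal.csv")[
      file.exists(file.path(cfg$out_dir,
                            c("track.csv", "points3d.csv", "signal.csv")))])))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Pipeline configuration
#'
#' Normalizes a configuration list (or YAML file) and fills defaults; see
#' arguments of the stage functions for the meaning of each entry.
#'
#' @param config List or YAML path.
#' @return Normalized configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(
    out_dir = tempfile("cbctmoco_run_"),
    seed = 1L,
    geometry = list(n_views = 200L, increment = 1.0, scan_time = 4,
                    sod = 800, sdd = 1200),
    phantom = NULL,
    noise = "none", fluence = 1e5,
    tracking_enabled = TRUE,
    seed_point = NULL,
    tracking = NULL,
    offset_deg = 90, triangulation_mode = "rectified_corrected",
    ref_index = 1L, signal_sigma = 2,
    grid_n = 128L, grid_spacing = 2, grid_center = c(0, 0, 0)
  )
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(cfg$geometry$detector) &&
      !inherits(cfg$geometry$detector, "detector_spec"))
    cfg$geometry$detector <- do.call(detector_spec,
                                     as.list(cfg$geometry$detector))
  if (is.null(cfg$phantom)) cfg$phantom <- phantom_spec()
  if (is.character(cfg$phantom)) {
    ph <- yaml::read_yaml(cfg$phantom)
    prim <- if (!is.null(ph$primitives))
      lapply(ph$primitives, function(p) do.call(ellipsoid, p)) else NULL
    cfg$phantom <- phantom_spec(
      primitives = prim,
      amplitude_mm = ph$amplitude_mm %||% 23,
      period_s = ph$period_s %||% 4,
      tracked_apex = ph$tracked_apex %||% c(-60, 0, -20))
  }
  if (is.null(cfg$tracking)) cfg$tracking <- tracking_config()
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
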