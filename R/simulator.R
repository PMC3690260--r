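#' Ellipsoid scene primitive
#'
#' Building block of the analytic thorax phantom. An ellipsoid is defined by
#' its center, semi-axes and a (possibly negative) attenuation coefficient;
#' negative attenuation is only allowed as an explicit subtraction primitive
#' used to carve cavities (e.g. air-filled lungs out of the body) and must be
#' flagged with `cavity = TRUE`. An optional axial clip plane `clip_z_min`
#' keeps only the part of the ellipsoid with `z >= clip_z_min`, which is how
#' dome-shaped diaphragm caps are modeled; the plane moves rigidly with the
#' primitive.
#'
#' @param center Length-3 center (mm).
#' @param semi_axes Length-3 positive semi-axes (mm).
#' @param attenuation Linear attenuation contribution (1/mm).
#' @param moving If `TRUE` the primitive is displaced by the breathing curve.
#' @param clip_z_min Optional lower clip plane (mm, world z at time 0).
#' @param cavity Must be `TRUE` when `attenuation < 0`.
#' @param label Optional name used in printing.
#' @return An object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, semi_axes, attenuation, moving = FALSE,
                      clip_z_min = NULL, cavity = FALSE, label = "") {
  if (length(center) != 3 || length(semi_axes) != 3)
    stop("center and semi_axes must have length 3")
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (attenuation < 0 && !cavity)
    stop("negative attenuation requires cavity = TRUE")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 attenuation = attenuation, moving = isTRUE(moving),
                 clip_z_min = clip_z_min, cavity = isTRUE(cavity),
                 label = label),
            class = "ellipsoid")
}

#' Dynamic thorax phantom specification
#'
#' The default layout emulates a rigidly breathing thorax: a water-like body
#' ellipsoid, two low-attenuation lungs (carved as cavities), a structured
#' heart (blood-pool chamber plus four high-contrast lesions staggered over
#' its z-extent), and two dome-shaped diaphragm caps (upper-half
#' ellipsoids), the right one 15 mm higher than the left as in real anatomy. Heart, lesions and diaphragm domes move along the
#' superior-inferior (z) axis following the breathing curve; everything else
#' is static. The apex of the tracked (right) hemidiaphragm dome is recorded
#' so ground truth is available at any time.
#'
#' @param primitives List of [ellipsoid()]s; default described above.
#' @param amplitude_mm Peak-to-peak breathing amplitude (mm), default 23.
#' @param period_s Breathing period (s), default 4 (one cycle per scan).
#' @param curve Breathing curve shape: `"sin2"` (default, one smooth cycle
#'   `A sin^2(pi t / T)`) or a function `f(t)` mapping time to a value in
#'   `[0, 1]` that is multiplied by the amplitude.
#' @param tracked_apex Apex of the tracked hemidiaphragm dome at time 0 (mm).
#' @return Object of class `phantom_spec`.
#' @examples
#' ph <- phantom_spec()
#' breathing_displacement(2, ph)   # peak of the cycle: 23 mm
#' @export
phantom_spec <- function(primitives = NULL, amplitude_mm = 23, period_s = 4,
                         curve = "sin2", tracked_apex = c(-60, 0, -20)) {
  if (amplitude_mm < 0) stop("amplitude must be non-negative")
  if (period_s <= 0) stop("period must be positive")
  if (is.null(primitives)) {
    mu_body <- 0.02; mu_lung <- 0.0002; mu_heart <- 0.03
    mu_lesion <- 0.05; mu_dia <- 0.02
    primitives <- list(
      ellipsoid(c(0, 0, 0),    c(150, 100, 180), mu_body, label = "body"),
      # lungs must not overlap at the midline (the heart sits in the gap)
      ellipsoid(c(-58, 0, 20), c(56, 60, 110),  mu_lung - mu_body,
                cavity = TRUE, label = "lung_right"),
      ellipsoid(c(58, 0, 20),  c(56, 60, 110),  mu_lung - mu_body,
                cavity = TRUE, label = "lung_left"),
      # heart with a blood-pool chamber and high-contrast lesions staggered
      # over its whole z-extent: every heart slice carries structure, as in
      # real cardiac anatomy
      ellipsoid(c(0, 20, 20),  c(40, 40, 50),   mu_heart - mu_body,
                moving = TRUE, label = "heart"),
      ellipsoid(c(5, 15, 20),  c(22, 22, 38),   -0.008,
                moving = TRUE, cavity = TRUE, label = "chamber"),
      ellipsoid(c(18, 25, 42), c(8, 8, 8),      mu_lesion - mu_heart,
                moving = TRUE, label = "lesion_a"),
      ellipsoid(c(-18, 12, 28), c(8, 8, 8),     mu_lesion - mu_heart,
                moving = TRUE, label = "lesion_b"),
      ellipsoid(c(16, 30, 8),  c(8, 8, 8),      mu_lesion - mu_heart,
                moving = TRUE, label = "lesion_c"),
      ellipsoid(c(-16, 18, -12), c(8, 8, 8),    mu_lesion - mu_heart,
                moving = TRUE, label = "lesion_d"),
      ellipsoid(c(-60, 0, -50), c(55, 55, 30),  mu_dia - mu_lung,
                moving = TRUE, clip_z_min = -50, label = "dome_right"),
      # the right hemidiaphragm sits higher than the left (liver underneath);
      # the 15 mm offset also separates the two contours in lateral views
      ellipsoid(c(60, 0, -65),  c(55, 55, 30),  mu_dia - mu_lung,
                moving = TRUE, clip_z_min = -65, label = "dome_left")
    )
  }
  structure(list(primitives = primitives, amplitude_mm = amplitude_mm,
                 period_s = period_s, curve = curve,
                 tracked_apex = as.numeric(tracked_apex)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d primitives (%d moving), %.3g mm p-p / %.3g s breathing\n",
              length(x$primitives), sum(vapply(x$primitives, `[[`, TRUE, "moving")),
              x$amplitude_mm, x$period_s))
  invisible(x)
}

#' Superior-inferior breathing displacement
#'
#' Smooth periodic displacement with range exactly `[0, amplitude_mm]`;
#' default shape `A sin^2(pi t / T)` (zero at scan start, peak at `T/2`).
#' Positive values mean the moving anatomy is displaced toward the inferior
#' direction (inhale pushes the diaphragm down, i.e. toward negative z).
#'
#' @param t Time(s) in seconds, vectorized, `t >= 0`.
#' @param spec A [phantom_spec()].
#' @return Displacement(s) in mm, `>= 0`.
#' @export
breathing_displacement <- function(t, spec) {
  if (any(t < 0)) stop("t must be non-negative")
  if (is.function(spec$curve)) {
    spec$amplitude_mm * spec$curve(t)
  } else {
    spec$amplitude_mm * sin(pi * t / spec$period_s)^2
  }
}

#' Evaluate the phantom scene at a time point
#'
#' Static primitives are returned unchanged; moving primitives are shifted by
#' minus the breathing displacement along z (inferior at inhale), including
#' their clip planes.
#'
#' @inheritParams breathing_displacement
#' @return List of [ellipsoid()]s.
#' @export
scene_at_time <- function(spec, t) {
  d <- breathing_displacement(t, spec)
  lapply(spec$primitives, function(e) {
    if (e$moving) {
      e$center[3] <- e$center[3] - d
      if (!is.null(e$clip_z_min)) e$clip_z_min <- e$clip_z_min - d
    }
    e
  })
}

#' True 3D position of the tracked diaphragm top
#'
#' @inheritParams breathing_displacement
#' @return Length-3 point (mm) or an n x 3 matrix for vector `t`.
#' @export
diaphragm_top_truth <- function(spec, t) {
  d <- breathing_displacement(t, spec)
  if (length(t) == 1L)
    return(spec$tracked_apex - c(0, 0, d))
  cbind(x = spec$tracked_apex[1], y = spec$tracked_apex[2],
        z = spec$tracked_apex[3] - d)
}

# chord length of unit-direction rays through one (possibly clipped)
# ellipsoid; src 3-vector, dirs n x 3 with unit rows; returns n lengths (mm)
ray_ellipsoid_chord <- function(src, dirs, e) {
  o <- (src - e$center) / e$semi_axes
  d <- sweep(dirs, 2, e$semi_axes, "/")
  A <- rowSums(d * d)
  B <- 2 * (d %*% o)[, 1]
  C <- sum(o * o) - 1
  disc <- B * B - 4 * A * C
  hit <- disc > 0
  len <- numeric(nrow(dirs))
  if (!any(hit)) return(len)
  sq <- sqrt(disc[hit])
  t1 <- (-B[hit] - sq) / (2 * A[hit])
  t2 <- (-B[hit] + sq) / (2 * A[hit])
  if (!is.null(e$clip_z_min)) {
    # intersect [t1, t2] with the half-space z >= clip_z_min along the ray
    dz <- dirs[hit, 3]
    z0 <- src[3]
    tcut <- (e$clip_z_min - z0) / ifelse(dz == 0, NA, dz)
    lo <- ifelse(is.na(tcut), ifelse(z0 >= e$clip_z_min, -Inf, Inf),
                 ifelse(dz > 0, tcut, -Inf))
    hi <- ifelse(is.na(tcut), ifelse(z0 >= e$clip_z_min, Inf, -Inf),
                 ifelse(dz > 0, Inf, tcut))
    t1 <- pmax(t1, lo)
    t2 <- pmin(t2, hi)
  }
  len[hit] <- pmax(t2 - t1, 0)
  len
}

#' Analytic forward projection of the dynamic phantom
#'
#' For every view the scene is evaluated at the view's timestamp and each
#' detector pixel receives the line integral `sum_k attenuation_k * chord_k`
#' over all primitives, with closed-form ray-ellipsoid (and clip-plane)
#' intersections. Noise-free by default; optionally Poisson counting noise at
#' a given fluence is applied to the line integrals.
#'
#' @param spec A [phantom_spec()].
#' @param geom A [circular_trajectory()] geometry.
#' @param noise `"none"` (default) or `"poisson"`.
#' @param fluence Unattenuated photon count per pixel for Poisson noise.
#' @param seed RNG seed, required when `noise = "poisson"`.
#' @return A `projection_stack`: list with `data` (array nv x nu x n_views,
#'   line-integral units) and `geometry`.
#' @export
forward_project <- function(spec, geom, noise = c("none", "poisson"),
                            fluence = 1e5, seed = NULL) {
  noise <- match.arg(noise)
  det <- geom$detector
  stack <- array(0, c(det$nv, det$nu, geom$n_views))
  uu <- (seq_len(det$nu) - 1 - det$u0) * det$spacing_u
  vv <- (seq_len(det$nv) - 1 - det$v0) * det$spacing_v
  U <- matrix(rep(uu, each = det$nv), det$nv, det$nu)
  V <- matrix(rep(vv, det$nu), det$nv, det$nu)
  for (i in seq_len(geom$n_views)) {
    fr <- detector_frame(geom, i)
    # pixel world positions relative to source
    dx <- geom$sdd * fr$axis[1] + U * fr$eu[1] + V * fr$ev[1]
    dy <- geom$sdd * fr$axis[2] + U * fr$eu[2] + V * fr$ev[2]
    dz <- geom$sdd * fr$axis[3] + U * fr$eu[3] + V * fr$ev[3]
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    dirs <- cbind(as.vector(dx / nrm), as.vector(dy / nrm), as.vector(dz / nrm))
    scene <- scene_at_time(spec, geom$timestamps[i])
    p <- numeric(nrow(dirs))
    for (e in scene)
      p <- p + e$attenuation * ray_ellipsoid_chord(fr$src, dirs, e)
    stack[, , i] <- p
  }
  if (noise == "poisson") {
    if (is.null(seed)) stop("Poisson noise requires an explicit seed")
    set.seed(seed)
    counts <- array(stats::rpois(length(stack), fluence * exp(-stack)),
                    dim = dim(stack))
    stack <- -log(pmax(counts, 1) / fluence)
  }
  structure(list(data = stack, geometry = geom), class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("projection_stack: %d views of %d x %d px, range [%.4g, %.4g]\n",
              d[3], d[2], d[1], min(x$data), max(x$data)))
  invisible(x)
}

#' Voxelize the phantom at a time point
#'
#' Each voxel center receives the sum of the attenuations of the primitives
#' containing it (cavities subtract). Used as motion-free ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param t Time (s).
#' @param grid Reconstruction grid from [make_grid()].
#' @return A `cbct_volume` (list of `data`, `spacing`, `origin`).
#' @export
render_volume <- function(spec, t, grid) {
  scene <- scene_at_time(spec, t)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  xs <- grid$origin[1] + (seq_len(nx) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(ny) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(nz) - 1) * grid$spacing[3]
  vol <- array(0, c(nx, ny, nz))
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  for (e in scene) {
    a2 <- e$semi_axes^2
    for (k in seq_len(nz)) {
      z <- zs[k]
      q <- (X[, , k] - e$center[1])^2 / a2[1] +
           (Y[, , k] - e$center[2])^2 / a2[2] +
           (z - e$center[3])^2 / a2[3]
      inside <- q <= 1
      if (!is.null(e$clip_z_min) && z < e$clip_z_min) inside[] <- FALSE
      vol[, , k] <- vol[, , k] + e$attenuation * inside
    }
  }
  structure(list(data = vol, spacing = rep_len(grid$spacing, 3),
                 origin = grid$origin), class = "cbct_volume")
}

#' Reconstruction / voxelization grid
#'
#' @param n Voxels per axis (scalar or length-3).
#' @param spacing Voxel size in mm (scalar or length-3).
#' @param center World center of the grid (mm).
#' @return List with `shape`, `spacing`, `origin` (center of voxel (1,1,1)).
#' @export
make_grid <- function(n = 128, spacing = 2, center = c(0, 0, 0)) {
  shape <- as.integer(rep_len(n, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- center - (shape - 1) / 2 * spacing
  list(shape = shape, spacing = spacing, origin = origin)
}

#' @export
print.cbct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("cbct_volume: %d x %d x %d @ %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}
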