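#' Flat-panel detector specification
#'
#' Describes the detector of a C-arm system: pixel grid, pixel pitch and
#' principal point. Pixel coordinates are 0-based and refer to pixel centers,
#' so the column coordinate u runs over `[0, nu)` and the row coordinate v
#' over `[0, nv)`. By image convention v grows toward the inferior direction
#' (downward in the displayed projection).
#'
#' @param nu,nv Detector columns and rows (pixels).
#' @param spacing_u,spacing_v Pixel pitch in mm/px.
#' @param u0,v0 Principal point (px); defaults to the detector center.
#' @return An object of class `detector_spec`.
#' @examples
#' det <- detector_spec()        # 640 x 480 at 0.616 mm/px
#' det$u0                        # 319.5
#' @export
detector_spec <- function(nu = 640L, nv = 480L,
                          spacing_u = 0.616, spacing_v = 0.616,
                          u0 = (nu - 1) / 2, v0 = (nv - 1) / 2) {
  nu <- as.integer(nu); nv <- as.integer(nv)
  if (nu <= 0L || nv <= 0L) stop("detector dimensions must be positive")
  if (spacing_u <= 0 || spacing_v <= 0) stop("pixel spacings must be positive")
  if (u0 < 0 || u0 >= nu || v0 < 0 || v0 >= nv)
    stop("principal point must lie inside the detector")
  structure(list(nu = nu, nv = nv,
                 spacing_u = spacing_u, spacing_v = spacing_v,
                 u0 = u0, v0 = v0),
            class = "detector_spec")
}

#' Circular short-scan acquisition geometry
#'
#' Builds the projection geometry of a circular C-arm trajectory. The world
#' frame is right-handed with z along the superior-inferior axis (= rotation
#' axis) and the isocenter at the origin. The source at gantry angle theta
#' sits at `(sod*cos(theta), sod*sin(theta), 0)`; the detector is
#' perpendicular to the source-isocenter line at distance `sdd` from the
#' source, with columns u perpendicular to z and rows v growing toward
#' decreasing world z (inferior). Timestamps are uniform on `[0, scan_time)`.
#'
#' @param n_views Number of projections (>= 2).
#' @param start_angle First gantry angle (deg).
#' @param increment Angular increment per view (deg).
#' @param sod Source-isocenter distance (mm).
#' @param sdd Source-detector distance (mm), must exceed `sod`.
#' @param scan_time Total scan duration (s).
#' @param detector A [detector_spec()].
#' @return An object of class `projection_geometry` with fields `n_views`,
#'   `matrices` (list of 3x4 projection matrices mapping world mm to detector
#'   px, homogeneous), `source_positions` (n x 3), `angles` (deg),
#'   `timestamps` (s), `detector`, `sod`, `sdd`, `increment`.
#' @details The third row of each matrix is the unit optical-axis direction,
#'   so the homogeneous scale of a projected point equals its depth along the
#'   optical axis in mm.
#' @examples
#' geom <- circular_trajectory(n_views = 200, increment = 1.0)
#' range(geom$angles)    # 0 .. 199 degrees
#' @export
circular_trajectory <- function(n_views, start_angle = 0, increment = 1.0,
                                sod = 800, sdd = 1200, scan_time = 4,
                                detector = detector_spec()) {
  n_views <- as.integer(n_views)
  if (n_views < 2L) stop("n_views must be at least 2")
  if (sod <= 0 || sdd <= sod) stop("require 0 < sod < sdd")
  if (scan_time <= 0) stop("scan_time must be positive")

  angles <- start_angle + increment * (seq_len(n_views) - 1)
  timestamps <- scan_time * (seq_len(n_views) - 1) / n_views
  fu <- sdd / detector$spacing_u
  fv <- sdd / detector$spacing_v
  K <- matrix(c(fu, 0, 0,
                0, fv, 0,
                detector$u0, detector$v0, 1), 3, 3)

  matrices <- vector("list", n_views)
  sources <- matrix(0, n_views, 3)
  for (i in seq_len(n_views)) {
    th <- angles[i] * pi / 180
    src <- c(sod * cos(th), sod * sin(th), 0)
    axis <- c(-cos(th), -sin(th), 0)          # optical axis, source -> isocenter
    eu <- c(-sin(th), cos(th), 0)             # detector column direction
    ev <- c(0, 0, -1)                         # rows grow toward inferior
    R <- rbind(eu, ev, axis)
    matrices[[i]] <- K %*% cbind(R, -R %*% src)
    sources[i, ] <- src
  }
  structure(list(n_views = n_views, matrices = matrices,
                 source_positions = sources, angles = angles,
                 timestamps = timestamps, detector = detector,
                 sod = sod, sdd = sdd, increment = increment),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection_geometry: %d views, %.6g deg span, sod %.6g / sdd %.6g mm\n",
              x$n_views, diff(range(x$angles)), x$sod, x$sdd))
  cat(sprintf("  detector %d x %d px @ %.6g x %.6g mm/px, scan %.6g s\n",
              x$detector$nu, x$detector$nv,
              x$detector$spacing_u, x$detector$spacing_v,
              max(x$timestamps)))
  invisible(x)
}

#' Project world points with a 3x4 projection matrix
#'
#' Homogeneous pinhole projection: `(u, v) = (h1/h3, h2/h3)` with
#' `h = P (X, 1)^T`. Points whose homogeneous scale is (numerically) zero lie
#' on the source plane and cannot be projected.
#'
#' @param P 3x4 projection matrix.
#' @param X Numeric length-3 vector or n x 3 matrix of world points (mm).
#' @return Length-2 vector `(u, v)` in px, or an n x 2 matrix.
#' @export
project_point <- function(P, X) {
  if (is.null(dim(X))) {
    h <- P %*% c(X, 1)
    if (abs(h[3]) < 1e-12) stop("point lies on the source plane (zero depth)")
    return(c(u = h[1] / h[3], v = h[2] / h[3]))
  }
  H <- cbind(X, 1) %*% t(P)
  if (any(abs(H[, 3]) < 1e-12)) stop("point lies on the source plane (zero depth)")
  cbind(u = H[, 1] / H[, 3], v = H[, 2] / H[, 3])
}

#' Back-project a detector pixel as a world ray
#'
#' @param geom A [circular_trajectory()] geometry.
#' @param view View index (1-based).
#' @param u,v Detector coordinates (px, 0-based pixel centers).
#' @return List with `origin` (the source position) and unit `direction`.
#' @export
pixel_ray <- function(geom, view, u, v) {
  det <- geom$detector
  th <- geom$angles[view] * pi / 180
  src <- geom$source_positions[view, ]
  axis <- c(-cos(th), -sin(th), 0)
  eu <- c(-sin(th), cos(th), 0)
  ev <- c(0, 0, -1)
  pix <- src + geom$sdd * axis +
    (u - det$u0) * det$spacing_u * eu +
    (v - det$v0) * det$spacing_v * ev
  d <- pix - src
  list(origin = src, direction = d / sqrt(sum(d^2)))
}

#' World position of detector pixel centers for one view
#'
#' Returns the detector basis needed to place pixels in the world frame.
#' @keywords internal
detector_frame <- function(geom, view) {
  th <- geom$angles[view] * pi / 180
  list(src = geom$source_positions[view, ],
       axis = c(-cos(th), -sin(th), 0),
       eu = c(-sin(th), cos(th), 0),
       ev = c(0, 0, -1))
}

#' Serialize acquisition geometry to JSON
#'
#' Writes the sidecar format used throughout the package: a single JSON
#' object with row-major matrices, source positions, angles, timestamps and
#' the detector specification. Full double precision is preserved.
#'
#' @param geom A `projection_geometry`.
#' @param path Output path.
#' @export
write_geometry <- function(geom, path) {
  obj <- list(
    n_views = geom$n_views,
    matrices = lapply(geom$matrices, function(m) as.vector(t(m))),
    sources = lapply(seq_len(geom$n_views),
                     function(i) geom$source_positions[i, ]),
    angles_deg = geom$angles,
    timestamps_s = geom$timestamps,
    sod = geom$sod, sdd = geom$sdd, increment = geom$increment,
    detector = list(nu = geom$detector$nu, nv = geom$detector$nv,
                    spacing_u = geom$detector$spacing_u,
                    spacing_v = geom$detector$spacing_v,
                    u0 = geom$detector$u0, v0 = geom$detector$v0)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @return `read_geometry` returns the `projection_geometry`.
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- do.call(detector_spec, as.list(obj$detector))
  mats <- lapply(seq_len(obj$n_views), function(i)
    matrix(unlist(obj$matrices[i, , drop = TRUE]), 3, 4, byrow = TRUE))
  if (is.list(obj$matrices))  # jagged fallback
    mats <- lapply(obj$matrices, function(m) matrix(unlist(m), 3, 4, byrow = TRUE))
  src <- obj$sources
  if (is.list(src)) src <- do.call(rbind, src)
  structure(list(n_views = as.integer(obj$n_views), matrices = mats,
                 source_positions = src, angles = obj$angles_deg,
                 timestamps = obj$timestamps_s, detector = det,
                 sod = obj$sod, sdd = obj$sdd, increment = obj$increment),
            class = "projection_geometry")
}
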