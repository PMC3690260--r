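#' Cosine, redundancy and ramp filtering of a projection stack
#'
#' Standard FDK pre-processing for a circular (short-scan) trajectory:
#' per-pixel cosine weighting, Parker redundancy weights when the angular
#' span is below 360 degrees, and row-wise ramp filtering by zero-padded FFT
#' convolution with the band-limited discrete ramp kernel (Ram-Lak) or the
#' Shepp-Logan kernel. Filtering is carried out on the virtual detector at
#' the isocenter, so the backprojection weight is `sod^2 / U^2`.
#'
#' @param stack A `projection_stack`.
#' @param geom Geometry (defaults to the stack's own).
#' @param filter `"ramlak"` (default) or `"shepplogan"`.
#' @param short_scan_weights Apply Parker weights (default `TRUE`; for spans
#'   of 360 degrees or more they reduce to the uniform full-scan weight 1/2).
#' @return A `projection_stack` of filtered projections (1/mm^2 units ready
#'   for backprojection).
#' @export
filter_projections <- function(stack, geom = stack$geometry,
                               filter = c("ramlak", "shepplogan"),
                               short_scan_weights = TRUE) {
  filter <- match.arg(filter)
  det <- geom$detector
  data <- stack$data
  nv <- det$nv; nu <- det$nu; n <- geom$n_views
  mag <- geom$sod / geom$sdd
  su <- det$spacing_u * mag   # virtual detector pitch at the isocenter
  sv <- det$spacing_v * mag
  uu <- (seq_len(nu) - 1 - det$u0) * su
  vv <- (seq_len(nv) - 1 - det$v0) * sv

  cosw <- geom$sod / sqrt(geom$sod^2 +
                          outer(vv^2, uu^2, "+"))  # nv x nu
  pw <- if (short_scan_weights) parker_weights(geom) else
    matrix(1, n, nu)

  # discrete ramp kernel on the virtual detector
  L <- 2^ceiling(log2(2 * nu))
  h <- numeric(L)
  ns <- c(0:(L / 2 - 1), -(L / 2):-1)
  if (filter == "ramlak") {
    h[ns == 0] <- 1 / (4 * su^2)
    odd <- ns %% 2 != 0
    h[odd] <- -1 / (pi^2 * ns[odd]^2 * su^2)
  } else {
    h <- -2 / (pi^2 * su^2 * (4 * ns^2 - 1))
  }
  H <- Re(stats::fft(h))

  out <- array(0, dim(data))
  for (i in seq_len(n)) {
    w <- cosw * matrix(pw[i, ], nv, nu, byrow = TRUE)
    img <- data[, , i] * w
    # ramp filter along u: FFT over zero-padded rows
    X <- matrix(0, L, nv)
    X[seq_len(nu), ] <- t(img)
    F <- stats::mvfft(X)
    Y <- Re(stats::mvfft(F * H, inverse = TRUE)) / L
    out[, , i] <- t(Y[seq_len(nu), , drop = FALSE]) * su
  }
  structure(list(data = out, geometry = geom), class = "projection_stack")
}

#' Parker redundancy weights for a short scan
#'
#' Per-view, per-detector-column redundancy weights for a circular scan
#' covering less than 360 degrees. Opposing rays measured twice within the
#' short-scan range receive smoothly feathered complementary weights
#' (weights of a conjugate ray pair sum to 1); a full 360-degree scan
#' reduces to the uniform weight 1/2 (every ray measured twice). The
#' half-overscan angle is derived from the actual span,
#' `(span - 180 deg) / 2`.
#'
#' @param geom A `projection_geometry`.
#' @return Matrix `n_views x nu` of weights in `[0, 1]`.
#' @export
parker_weights <- function(geom) {
  det <- geom$detector
  nu <- det$nu
  su <- det$spacing_u * geom$sod / geom$sdd
  # fan angle sign: positive gamma = side of the detector that leads the
  # rotation (so the conjugate of (beta, gamma) is (beta + pi - 2 gamma,
  # -gamma) within the scan)
  gamma <- atan((seq_len(nu) - 1 - det$u0) * su / geom$sod) *
    sign(geom$increment) * -1
  span <- geom$n_views * abs(geom$increment) * pi / 180
  if (span >= 2 * pi - 1e-9)
    return(matrix(0.5, geom$n_views, nu))
  G <- (span - pi) / 2
  if (G <= 0) return(matrix(1, geom$n_views, nu))
  W <- matrix(1, geom$n_views, nu)
  beta_all <- (geom$angles - geom$angles[1]) * pi / 180
  for (i in seq_len(geom$n_views)) {
    beta <- beta_all[i]
    w <- rep(1, nu)
    r1 <- beta >= 0 & beta < 2 * (G - gamma)
    w[r1] <- sin(pi / 4 * beta / (G - gamma[r1]))^2
    r3 <- beta > pi - 2 * gamma & beta <= pi + 2 * G
    w[r3] <- sin(pi / 4 * (pi + 2 * G - beta) / (G + gamma[r3]))^2
    w[beta > pi + 2 * G | beta < 0] <- 0
    W[i, ] <- w
  }
  W
}

#' Per-view voxel shift under a respiratory motion model
#'
#' Maps a voxel of the reference grid to its position at a view's
#' acquisition time. The constant model shifts every voxel by the signal
#' value (`(0, 0, -r_i)`: the anatomy sits inferior of its reference
#' position by the current SI displacement). The linear model scales the
#' shift with height: `shift_z = -m (z_max - z)` for `z <= z_max` and 0
#' above, with slope `m = r_i / (z_max - z_dia,i)` — full diaphragm motion
#' at the diaphragm, none at the chosen zero-motion height `z_max`.
#'
#' @param model Either `list(kind = "constant", r = <per-view mm>)` or
#'   `list(kind = "linear", r = <per-view scaled mm>, z_dia = <per-view mm>,
#'   z_max = <mm>)`.
#' @param view View index (1-based).
#' @param pos Voxel position `(x, y, z)` (mm) on the reference grid.
#' @return Shifted position at the view's acquisition time.
#' @export
voxel_shift <- function(model, view, pos) {
  if (model$kind == "constant") {
    pos[3] <- pos[3] - model$r[view]
  } else if (model$kind == "linear") {
    if (any(model$z_max == model$z_dia))
      stop("z_max must differ from the diaphragm z")
    m <- model$r[view] / (model$z_max - model$z_dia[view])
    if (pos[3] <= model$z_max)
      pos[3] <- pos[3] - m * (model$z_max - pos[3])
  } else stop("unknown motion model kind")
  pos
}

#' Motion model constructors
#'
#' @param signal A `respiration_signal` (per-view SI displacement, mm).
#' @return A motion model usable by [voxel_shift()] / [backproject()].
#' @export
constant_motion_model <- function(signal) {
  list(kind = "constant", r = signal$r)
}

#' @rdname constant_motion_model
#' @param scale Linear diaphragm-to-target scale from
#'   [estimate_linear_scale()].
#' @param diaphragm_z Per-view diaphragm-top z (mm).
#' @param z_max Height at which motion is assumed zero (mm), e.g. the lung
#'   top.
#' @export
linear_motion_model <- function(signal, scale, diaphragm_z, z_max) {
  if (any(z_max == diaphragm_z)) stop("z_max must differ from diaphragm z")
  list(kind = "linear", r = scale * signal$r, z_dia = diaphragm_z,
       z_max = z_max)
}

#' Motion-compensated FDK backprojection
#'
#' Voxel-driven distance-weighted backprojection of filtered projections.
#' For every view each voxel center of the reference grid is first shifted to
#' its position at the view's acquisition time with [voxel_shift()] (so the
#' accumulated volume lives at the reference respiratory phase), then
#' projected onto the detector, sampled bilinearly and accumulated with the
#' FDK weight `dbeta * sod^2 / U^2`, where `U` is the shifted voxel's depth
#' along the view's optical axis. Projections falling outside the detector
#' contribute nothing. With `motion = NULL` every shift is zero and the
#' result is standard FDK (identical code path).
#'
#' @param filtered Filtered `projection_stack` from [filter_projections()].
#' @param geom Geometry (defaults to the stack's).
#' @param motion Optional motion model ([constant_motion_model()] /
#'   [linear_motion_model()]).
#' @param grid Reconstruction grid from [make_grid()].
#' @return A `cbct_volume`.
#' @export
backproject <- function(filtered, geom = filtered$geometry, motion = NULL,
                        grid = make_grid()) {
  det <- geom$detector
  n <- geom$n_views
  if (is.null(motion)) motion <- list(kind = "constant", r = numeric(n))
  if (motion$kind == "constant") {
    mtype <- 0L
    m1 <- rep_len(motion$r, n); m2 <- numeric(n); m3 <- 0
  } else {
    mtype <- 1L
    m1 <- rep_len(motion$r, n); m2 <- rep_len(motion$z_dia, n)
    m3 <- motion$z_max
    if (any(m3 == m2)) stop("z_max must differ from diaphragm z")
  }
  P <- do.call(rbind, lapply(geom$matrices, function(m) as.vector(t(m))))
  th <- geom$angles * pi / 180
  axes <- cbind(-cos(th), -sin(th), 0)
  dbeta <- abs(geom$increment) * pi / 180
  vol <- cpp_backproject(filtered$data, P, geom$source_positions, axes,
                         geom$sod, dbeta, grid$shape, grid$spacing,
                         grid$origin, mtype, m1, m2, m3)
  structure(list(data = vol, spacing = grid$spacing, origin = grid$origin),
            class = "cbct_volume")
}

#' Filtered backprojection pipeline
#'
#' Convenience composition of [filter_projections()] and [backproject()].
#'
#' @param stack Raw `projection_stack`.
#' @param geom Geometry (defaults to the stack's).
#' @param signal Optional `respiration_signal` for compensation.
#' @param model_kind `"none"`, `"constant"` or `"linear"`.
#' @param grid Output grid.
#' @param filter Ramp filter name.
#' @param scale,diaphragm_z,z_max Parameters of the linear model (see
#'   [linear_motion_model()]).
#' @return A `cbct_volume`.
#' @export
reconstruct <- function(stack, geom = stack$geometry, signal = NULL,
                        model_kind = c("none", "constant", "linear"),
                        grid = make_grid(), filter = "ramlak",
                        scale = 1, diaphragm_z = NULL, z_max = NULL) {
  model_kind <- match.arg(model_kind)
  filt <- filter_projections(stack, geom, filter = filter)
  motion <- switch(model_kind,
    none = NULL,
    constant = constant_motion_model(signal),
    linear = linear_motion_model(signal, scale, diaphragm_z, z_max))
  backproject(filt, geom, motion, grid)
}
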