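#' Detector-space parabola model of the diaphragm contour
#'
#' The hemidiaphragm contour in a projection image is modeled as
#' `v = a u^2 + b u + c` (detector px, v-axis pointing down). A tracked dome
#' therefore has `a > 0` and its apex — the topmost contour point — is the
#' vertex at `u* = -b / (2a)`, `v* = c - b^2 / (4a)`.
#'
#' @param a,b,c Coefficients; `a` must be non-zero.
#' @return Object of class `parabola_model`.
#' @export
parabola_model <- function(a, b, c) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  if (!is.finite(a) || a == 0) stop("parabola requires a != 0")
  if (!is.finite(b) || !is.finite(c)) stop("parabola coefficients must be finite")
  structure(list(a = a, b = b, c = c), class = "parabola_model")
}

#' @rdname parabola_model
#' @param model A `parabola_model`.
#' @return `parabola_vertex` returns the vertex `(u, v)`.
#' @export
parabola_vertex <- function(model) {
  u <- -model$b / (2 * model$a)
  c(u = u, v = model$c - model$b^2 / (4 * model$a))
}

#' @export
print.parabola_model <- function(x, ...) {
  vx <- parabola_vertex(x)
  cat(sprintf("parabola v = %.6g u^2 + %.6g u + %.6g, vertex (%.2f, %.2f) px\n",
              x$a, x$b, x$c, vx[1], vx[2]))
  invisible(x)
}

#' RANSAC configuration for parabola fitting
#'
#' @param n_models Number of random 3-point models to draw (default 20000).
#' @param inlier_tol Inlier distance in px (vertical distance to the model;
#'   default 1, i.e. only points within one pixel count as inliers).
#' @param min_points Minimum usable points (3).
#' @param refit Least-squares refit on the final inlier set (default `TRUE`).
#' @export
ransac_config <- function(n_models = 20000L, inlier_tol = 1, min_points = 3L,
                          refit = TRUE) {
  if (n_models < 1) stop("n_models must be >= 1")
  if (inlier_tol <= 0) stop("inlier_tol must be positive")
  structure(list(n_models = as.integer(n_models), inlier_tol = inlier_tol,
                 min_points = as.integer(min_points), refit = isTRUE(refit)),
            class = "ransac_config")
}

# separable gaussian blur with reflected boundaries
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    # convolve along rows (dim 1) with reflect padding
    n <- nrow(m); r <- (length(kern) - 1L) / 2L
    idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern))
      out <- out + kern[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img, k)), k))
}

# Canny edge detection on a small image patch.
# Returns a data.frame of 0-based (u, v) edge coordinates relative to the
# patch, with optional sub-pixel refinement of v by parabolic interpolation
# of the gradient magnitude along the column.
canny_edges <- function(img, sigma = 2, low_frac = 0.1, high_frac = 0.3,
                        subpixel = TRUE) {
  sm <- gauss_blur(img, sigma)
  nv <- nrow(sm); nu <- ncol(sm)
  if (nv < 3 || nu < 3) return(data.frame(u = numeric(0), v = numeric(0)))
  # Sobel gradients (v = rows, u = cols)
  pad <- function(m) m[c(1, seq_len(nv), nv), c(1, seq_len(nu), nu)]
  p <- pad(sm)
  ix <- function(dv, du) p[seq_len(nv) + 1 + dv, seq_len(nu) + 1 + du]
  gu <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  gv <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  mag <- sqrt(gu^2 + gv^2)
  rng <- max(mag)
  if (rng <= 0) return(data.frame(u = numeric(0), v = numeric(0)))
  # non-maximum suppression with direction quantized to 4 sectors
  ang <- atan2(gv, gu)  # [-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E/W 1:NE/SW 2:N/S 3:NW/SE
  mpad <- matrix(0, nv + 2, nu + 2); mpad[2:(nv + 1), 2:(nu + 1)] <- mag
  sh <- function(dv, du) mpad[seq_len(nv) + 1 + dv, seq_len(nu) + 1 + du]
  n1 <- sh(0, 1) * (sector == 0) + sh(1, 1) * (sector == 1) +
        sh(1, 0) * (sector == 2) + sh(1, -1) * (sector == 3)
  n2 <- sh(0, -1) * (sector == 0) + sh(-1, -1) * (sector == 1) +
        sh(-1, 0) * (sector == 2) + sh(-1, 1) * (sector == 3)
  peak <- mag >= n1 & mag >= n2
  strong <- peak & mag >= high_frac * rng
  weak <- peak & mag >= low_frac * rng
  # hysteresis: grow strong through weak (8-connected flood)
  cur <- strong
  repeat {
    cpad <- matrix(FALSE, nv + 2, nu + 2); cpad[2:(nv + 1), 2:(nu + 1)] <- cur
    nb <- cpad[1:nv, 1:nu] | cpad[1:nv, 2:(nu + 1)] | cpad[1:nv, 3:(nu + 2)] |
          cpad[2:(nv + 1), 1:nu] | cpad[2:(nv + 1), 3:(nu + 2)] |
          cpad[3:(nv + 2), 1:nu] | cpad[3:(nv + 2), 2:(nu + 1)] |
          cpad[3:(nv + 2), 3:(nu + 2)]
    grown <- cur | (weak & nb)
    if (identical(grown, cur)) break
    cur <- grown
  }
  idx <- which(cur, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(u = numeric(0), v = numeric(0)))
  vpos <- idx[, 1] - 1
  if (subpixel) {
    ok <- idx[, 1] > 1 & idx[, 1] < nv
    m0 <- mag[idx]
    up <- mag[cbind(pmax(idx[, 1] - 1, 1), idx[, 2])]
    dn <- mag[cbind(pmin(idx[, 1] + 1, nv), idx[, 2])]
    den <- up - 2 * m0 + dn
    dv <- ifelse(ok & den < 0, 0.5 * (up - dn) / den, 0)
    vpos <- vpos + pmax(pmin(dv, 0.5), -0.5)
  }
  data.frame(u = idx[, 2] - 1, v = vpos)
}

#' Rectangular region of interest around a seed point
#'
#' Centered symmetrically on the seed; dimensions default to 250 x 55 px for
#' a 640 x 480 detector and scale linearly with the detector resolution. The
#' box is clipped to the image bounds.
#'
#' @param seed Seed point `(u, v)` in px.
#' @param width,height ROI size in px at the 640 x 480 reference resolution.
#' @param detector A [detector_spec()] (for bounds and scaling).
#' @return List with fields `u_min`, `u_max`, `v_min`, `v_max` (0-based,
#'   inclusive).
#' @export
rect_roi <- function(seed, width = 250, height = 55,
                     detector = detector_spec()) {
  w <- width * detector$nu / 640
  h <- height * detector$nv / 480
  r <- list(u_min = seed[1] - w / 2, u_max = seed[1] + w / 2,
            v_min = seed[2] - h / 2, v_max = seed[2] + h / 2)
  r$u_min <- max(r$u_min, 0); r$v_min <- max(r$v_min, 0)
  r$u_max <- min(r$u_max, detector$nu - 1)
  r$v_max <- min(r$v_max, detector$nv - 1)
  if (r$u_min > r$u_max || r$v_min > r$v_max)
    stop("ROI does not intersect the image")
  r
}

#' Parabolic band region of interest
#'
#' Membership predicate: a point `(u, v)` belongs to the band if its vertical
#' distance to the previous frame's model is at most `band_height / 2` and
#' its `u` lies in the given range (the rectangular ROI's u-range).
#'
#' @param prev A `parabola_model` from the previous frame.
#' @param band_height Band height in px (default 21, i.e. +/- 10.5 px).
#' @param u_range Length-2 u interval.
#' @return Function `(u, v) -> logical`.
#' @export
parabolic_roi <- function(prev, band_height = 21, u_range = c(-Inf, Inf)) {
  function(u, v) {
    pred <- prev$a * u^2 + prev$b * u + prev$c
    abs(v - pred) <= band_height / 2 & u >= u_range[1] & u <= u_range[2]
  }
}

#' Extract candidate contour points inside a region of interest
#'
#' The ROI's bounding box (plus a small margin for filter support) is cut out
#' of the image, smoothed with a gaussian low-pass filter, and edges are
#' detected with the Canny detector (hysteresis thresholds as fractions of
#' the patch's maximum gradient magnitude). Edge pixels outside the ROI are
#' discarded.
#'
#' @param image Projection image (matrix, rows = v, cols = u).
#' @param roi Either a rectangle from [rect_roi()] or a list
#'   `list(rect = <bounding rectangle>, member = <predicate>)` as used for
#'   the parabolic band.
#' @param gauss_sigma Smoothing sigma in px (default 1; the tangential-onset
#'   edge profile of a dome contour biases inward with increasing smoothing,
#'   so keep the scale small for low-noise data).
#' @param canny_low,canny_high Hysteresis thresholds as fractions of the
#'   patch's gradient range (defaults 0.1 / 0.3).
#' @param subpixel Refine the row coordinate of each edge point by parabolic
#'   interpolation of the gradient magnitude (default `TRUE`).
#' @return Data frame of image-coordinate edge points `(u, v)`, possibly
#'   empty.
#' @export
extract_edge_points <- function(image, roi, gauss_sigma = 1,
                                canny_low = 0.1, canny_high = 0.3,
                                subpixel = TRUE) {
  if (!is.null(roi$rect)) { rect <- roi$rect; member <- roi$member }
  else { rect <- roi; member <- NULL }
  nv <- nrow(image); nu <- ncol(image)
  m <- ceiling(3 * gauss_sigma) + 1
  u0 <- max(floor(rect$u_min) - m, 0); u1 <- min(ceiling(rect$u_max) + m, nu - 1)
  v0 <- max(floor(rect$v_min) - m, 0); v1 <- min(ceiling(rect$v_max) + m, nv - 1)
  if (u0 > u1 || v0 > v1) stop("ROI does not intersect the image")
  patch <- image[(v0 + 1):(v1 + 1), (u0 + 1):(u1 + 1), drop = FALSE]
  pts <- canny_edges(patch, sigma = gauss_sigma, low_frac = canny_low,
                     high_frac = canny_high, subpixel = subpixel)
  if (!nrow(pts)) return(pts)
  pts$u <- pts$u + u0
  pts$v <- pts$v + v0
  keep <- pts$u >= rect$u_min & pts$u <= rect$u_max &
          pts$v >= rect$v_min & pts$v <= rect$v_max
  if (!is.null(member)) keep <- keep & member(pts$u, pts$v)
  pts[keep, , drop = FALSE]
}

# closed-form parabola through three points with distinct u
fit3 <- function(u1, v1, u2, v2, u3, v3) {
  s12 <- (v2 - v1) / (u2 - u1)
  s13 <- (v3 - v1) / (u3 - u1)
  a <- (s13 - s12) / (u3 - u2)
  b <- s12 - a * (u1 + u2)
  c <- v1 - a * u1^2 - b * u1
  list(a = a, b = b, c = c)
}

#' Robust parabola fit by RANSAC
#'
#' Draws `n_models` random 3-point samples, fits the interpolating parabola
#' to each in closed form, and scores models by the number of inliers (points
#' within `inlier_tol` vertical distance). The model with the most inliers
#' wins; ties are broken by the smaller mean inlier residual, then by the
#' lower model index. Optionally the winner is refit by least squares on its
#' inlier set.
#'
#' @param points Data frame with columns `u`, `v` (>= 3 rows with at least 3
#'   distinct `u`).
#' @param cfg A [ransac_config()].
#' @param rng_seed Integer seed making the sampling reproducible.
#' @return List with `model` (`parabola_model`), `n_inliers`, and `inliers`
#'   (row indices into `points`).
#' @export
fit_parabola_ransac <- function(points, cfg = ransac_config(), rng_seed = 1L) {
  n <- nrow(points)
  if (n < cfg$min_points || length(unique(points$u)) < 3)
    stop("parabola fit failure: need at least 3 points with distinct u")
  u <- points$u; v <- points$v
  set.seed(rng_seed)
  N <- cfg$n_models
  i1 <- sample.int(n, N, replace = TRUE)
  i2 <- sample.int(n, N, replace = TRUE)
  i3 <- sample.int(n, N, replace = TRUE)
  ok <- u[i1] != u[i2] & u[i1] != u[i3] & u[i2] != u[i3]
  f <- fit3(u[i1], v[i1], u[i2], v[i2], u[i3], v[i3])
  a <- f$a; b <- f$b; cc <- f$c
  ok <- ok & is.finite(a) & a != 0
  if (!any(ok)) stop("parabola fit failure: all samples degenerate")

  best <- NULL
  chunk <- 2000L
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    sel <- which(ok[s:e]) + (s - 1L)
    if (!length(sel)) next
    # residual matrix: models x points
    Rm <- outer(a[sel], u^2) + outer(b[sel], u) + cc[sel] -
      matrix(v, length(sel), n, byrow = TRUE)
    In <- abs(Rm) <= cfg$inlier_tol
    cnt <- rowSums(In)
    mres <- rowSums(abs(Rm) * In) / pmax(cnt, 1L)
    o <- order(-cnt, mres, sel)[1]
    cand <- list(idx = sel[o], count = cnt[o], mres = mres[o])
    if (is.null(best) || cand$count > best$count ||
        (cand$count == best$count && cand$mres < best$mres))
      best <- cand
  }
  j <- best$idx
  model <- parabola_model(a[j], b[j], cc[j])
  resid <- abs(model$a * u^2 + model$b * u + model$c - v)
  inliers <- which(resid <= cfg$inlier_tol)
  if (cfg$refit && length(inliers) >= 3 &&
      length(unique(u[inliers])) >= 3) {
    X <- cbind(u[inliers]^2, u[inliers], 1)
    beta <- qr.solve(X, v[inliers])
    if (is.finite(beta[1]) && beta[1] != 0)
      model <- parabola_model(beta[1], beta[2], beta[3])
  }
  list(model = model, n_inliers = length(inliers), inliers = inliers)
}

#' Tracking configuration
#'
#' @param ransac A [ransac_config()].
#' @param gauss_sigma,canny_low,canny_high Edge-extraction parameters, see
#'   [extract_edge_points()].
#' @param band_height Parabolic ROI height (px, default 21).
#' @param roi_width,roi_height Rectangular ROI size at 640 x 480 (default
#'   250 x 55).
#' @param motion_factor Constraint (i): a candidate vertex may move at most
#'   `motion_factor` times the running mean |delta u*| per frame.
#' @param motion_floor_px Floor (px) below which constraint (i) never fires;
#'   prevents lock-up early in the sequence.
#' @param deformation_limit Constraint (ii): maximum relative change of the
#'   curvature coefficient `a` between frames (default 0.05).
#' @param free_window_deg Constraint (iii): half-width of the free-motion
#'   window around the turning point (views whose optical axis is within
#'   this angle of the anterior-posterior direction; default 15).
#' @param direction Initial horizontal motion direction: `"auto"` (estimate
#'   from the first frames), `"left"`, `"right"`, or `"free"` (disable the
#'   direction constraint).
#' @export
tracking_config <- function(ransac = ransac_config(), gauss_sigma = 1,
                            canny_low = 0.1, canny_high = 0.3,
                            band_height = 21, roi_width = 250,
                            roi_height = 55, motion_factor = 2,
                            motion_floor_px = 3, deformation_limit = 0.05,
                            free_window_deg = 15,
                            direction = c("auto", "left", "right", "free")) {
  direction <- match.arg(direction)
  structure(list(ransac = ransac, gauss_sigma = gauss_sigma,
                 canny_low = canny_low, canny_high = canny_high,
                 band_height = band_height, roi_width = roi_width,
                 roi_height = roi_height, motion_factor = motion_factor,
                 motion_floor_px = motion_floor_px,
                 deformation_limit = deformation_limit,
                 free_window_deg = free_window_deg, direction = direction),
            class = "tracking_config")
}

#' Apply tracking constraints to a candidate model
#'
#' Implements the three acceptance rules used while chaining models from
#' frame to frame: (i) the horizontal vertex motion is limited by the average
#' motion in previous frames (times `motion_factor`, with a small floor),
#' (ii) the contour deformation — the relative change of the curvature
#' coefficient `a` — is limited to `deformation_limit` (5 %), and (iii) the
#' horizontal motion direction must match the expected direction derived
#' from the rotation, except inside the free-motion window around the
#' turning point.
#'
#' @param candidate Candidate `parabola_model` for the current frame.
#' @param state Tracking state: list with `prev_model`, `mean_abs_du`,
#'   `expected_direction` (`-1`, `+1`, or `0` for free), `n_frames`.
#' @param cfg A [tracking_config()].
#' @return List with `model`, `accepted` (logical), `reason` (string, `""`
#'   when accepted). On rejection `model` is `NULL`; the caller substitutes
#'   the fallback.
#' @export
constrain <- function(candidate, state, cfg = tracking_config()) {
  prev <- state$prev_model
  du <- parabola_vertex(candidate)["u"] - parabola_vertex(prev)["u"]
  limit <- max(cfg$motion_factor * state$mean_abs_du, cfg$motion_floor_px)
  if (abs(du) > limit)
    return(list(model = NULL, accepted = FALSE, reason = "motion"))
  if (abs(candidate$a - prev$a) / abs(prev$a) > cfg$deformation_limit)
    return(list(model = NULL, accepted = FALSE, reason = "deformation"))
  if (state$expected_direction != 0 && du != 0 &&
      sign(du) != state$expected_direction)
    return(list(model = NULL, accepted = FALSE, reason = "direction"))
  list(model = candidate, accepted = TRUE, reason = "")
}

# fallback when a candidate is rejected: keep the previous curvature a and
# refit b, c by least squares on the current inlier points
constrained_refit <- function(prev, points, inliers) {
  if (length(inliers) >= 2) {
    u <- points$u[inliers]; v <- points$v[inliers] - prev$a * u^2
    X <- cbind(u, 1)
    beta <- tryCatch(qr.solve(X, v), error = function(e) NULL)
    if (!is.null(beta) && all(is.finite(beta)))
      return(parabola_model(prev$a, beta[1], beta[2]))
  }
  prev
}

#' Track the diaphragm contour through a projection sequence
#'
#' Frame 0 uses a rectangular ROI centered on the user seed; subsequent
#' frames use a parabolic band around the previous model (centered on the
#' previous vertex), RANSAC parabola fitting, and the constraints of
#' [constrain()]. On a constraint rejection the previous curvature is kept
#' and only `b`, `c` are refit on the current inliers; on a complete fit
#' failure the previous model is carried over (flagged). Deterministic for a
#' fixed `rng_seed`.
#'
#' @param stack A `projection_stack`.
#' @param seed Seed point `(u, v)` near the apex in frame 0 (px).
#' @param cfg A [tracking_config()].
#' @param rng_seed Integer seed for the RANSAC sampling.
#' @return A `diaphragm_track` data frame with one row per frame: `frame`
#'   (0-based), `a`, `b`, `c`, `u_vertex`, `v_vertex`, `n_inliers`,
#'   `constrained` (`"ok"`, `"motion"`, `"deformation"`, `"direction"`, or
#'   `"carried"`).
#' @export
track_sequence <- function(stack, seed, cfg = tracking_config(),
                           rng_seed = 1L) {
  geom <- stack$geometry
  det <- geom$detector
  n <- geom$n_views
  if (seed[1] < 0 || seed[1] >= det$nu || seed[2] < 0 || seed[2] >= det$nv)
    stop("seed point outside frame 0")

  # constraint (iii): expected u-direction flips at the turning point, the
  # view whose optical axis is closest to the anterior-posterior (y) axis;
  # free motion within +/- free_window_deg of it
  ap_dist <- abs(abs(sin(geom$angles * pi / 180)) - 1)  # 0 at AP views
  turning <- which.min(ap_dist)
  in_free <- abs(geom$angles - geom$angles[turning]) <= cfg$free_window_deg

  out <- data.frame(frame = seq_len(n) - 1L, a = NA_real_, b = NA_real_,
                    c = NA_real_, u_vertex = NA_real_, v_vertex = NA_real_,
                    n_inliers = NA_integer_, constrained = "",
                    stringsAsFactors = FALSE)
  state <- NULL
  dir0 <- switch(cfg$direction, left = -1, right = 1, free = 0, auto = NA)
  du_hist <- numeric(0)
  set.seed(rng_seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, n)

  prev_vertex <- seed
  for (i in seq_len(n)) {
    img <- stack$data[, , i]
    # a wild fit can put the previous vertex outside the image; keep the
    # search window on the detector
    prev_vertex <- c(min(max(prev_vertex[1], 0), det$nu - 1),
                     min(max(prev_vertex[2], 0), det$nv - 1))
    if (is.null(state)) {
      roi <- rect_roi(prev_vertex, cfg$roi_width, cfg$roi_height, det)
    } else {
      rect <- rect_roi(prev_vertex, cfg$roi_width, cfg$roi_height, det)
      band <- parabolic_roi(state$prev_model, cfg$band_height,
                            c(rect$u_min, rect$u_max))
      vx <- parabola_vertex(state$prev_model)
      half <- cfg$band_height / 2
      uu <- c(rect$u_min, rect$u_max)
      vpred <- state$prev_model$a * uu^2 + state$prev_model$b * uu +
        state$prev_model$c
      roi <- list(rect = list(u_min = rect$u_min, u_max = rect$u_max,
                              v_min = max(min(vx[2], vpred) - half, 0),
                              v_max = min(max(vpred) + half, det$nv - 1)),
                  member = band)
    }
    fit <- tryCatch({
      pts <- extract_edge_points(img, roi, cfg$gauss_sigma, cfg$canny_low,
                                 cfg$canny_high)
      f <- fit_parabola_ransac(pts, cfg$ransac, frame_seeds[i])
      f$points <- pts
      f
    }, error = function(e) NULL)

    if (is.null(fit)) {                      # carry previous model over
      if (is.null(state)) stop("tracking failed on the first frame")
      model <- state$prev_model
      flag <- "carried"
      n_inl <- 0L
    } else if (is.null(state)) {             # first frame: no constraints
      model <- fit$model
      flag <- "ok"
      n_inl <- fit$n_inliers
    } else {
      st <- state
      if (!is.na(dir0)) {
        st$expected_direction <- if (in_free[i]) 0
          else if (i <= turning) dir0 else -dir0
      } else st$expected_direction <- 0      # auto: free until estimated
      chk <- constrain(fit$model, st, cfg)
      if (chk$accepted) {
        model <- fit$model
        flag <- "ok"
      } else {
        model <- constrained_refit(state$prev_model, fit$points, fit$inliers)
        flag <- chk$reason
      }
      n_inl <- fit$n_inliers
    }

    vx <- parabola_vertex(model)
    out$a[i] <- model$a; out$b[i] <- model$b; out$c[i] <- model$c
    out$u_vertex[i] <- vx[1]; out$v_vertex[i] <- vx[2]
    out$n_inliers[i] <- n_inl
    out$constrained[i] <- flag

    if (!is.null(state)) {
      du_hist <- c(du_hist, abs(vx[1] - parabola_vertex(state$prev_model)["u"]))
      if (is.na(dir0) && length(du_hist) == 5L) {
        drift <- vx[1] - out$u_vertex[1]
        dir0 <- if (drift > 0) 1 else if (drift < 0) -1 else 0
      }
    }
    state <- list(prev_model = model,
                  mean_abs_du = if (length(du_hist)) mean(du_hist) else 0,
                  expected_direction = 0, n_frames = i)
    prev_vertex <- vx
  }
  class(out) <- c("diaphragm_track", "data.frame")
  out
}

#' @export
print.diaphragm_track <- function(x, ...) {
  cat(sprintf("diaphragm_track: %d frames, vertex u in [%.1f, %.1f], v in [%.1f, %.1f] px\n",
              nrow(x), min(x$u_vertex), max(x$u_vertex),
              min(x$v_vertex), max(x$v_vertex)))
  cat(sprintf("  accepted: %d, constrained fallback: %d, carried: %d\n",
              sum(x$constrained == "ok"),
              sum(!x$constrained %in% c("ok", "carried")),
              sum(x$constrained == "carried")))
  invisible(x)
}
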