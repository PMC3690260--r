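#' Per-slice structural similarity between two volumes
#'
#' Mean SSIM (Wang et al. 2004) per slice, computed with a gaussian window
#' (luminance x contrast x structure with the usual stabilization constants
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`). The dynamic range `L` defaults to the
#' joint max-minus-min of both (cropped) volumes. Values lie in `[-1, 1]`;
#' 1 is attained only for identical images. To suppress the influence of a
#' static background the comparison is typically restricted to a crop such
#' as the heart bounding box.
#'
#' @param vol_a,vol_b `cbct_volume`s of equal shape.
#' @param crop Optional integer crop `list(x = c(i0, i1), y = ..., z = ...)`
#'   (1-based, inclusive) applied to both volumes.
#' @param axis Slice orientation: `"xy"` (slices along z) or `"xz"` (slices
#'   along y).
#' @param sigma Gaussian window sigma in px (default 1.5).
#' @param k1,k2 Stabilization constants (defaults 0.01, 0.03).
#' @param L Dynamic range; default joint `max - min` (1 if that is zero).
#' @return Numeric vector of per-slice mean SSIM values.
#' @export
ssim_slices <- function(vol_a, vol_b, crop = NULL, axis = c("xy", "xz"),
                        sigma = 1.5, k1 = 0.01, k2 = 0.03, L = NULL) {
  axis <- match.arg(axis)
  a <- vol_a$data; b <- vol_b$data
  if (!identical(dim(a), dim(b))) stop("volume shapes differ")
  if (!is.null(crop)) {
    a <- a[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], crop$z[1]:crop$z[2]]
    b <- b[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], crop$z[1]:crop$z[2]]
  }
  if (is.null(L)) {
    L <- max(a, b) - min(a, b)
    if (L <= 0) L <- 1
  }
  nsl <- if (axis == "xy") dim(a)[3] else dim(a)[2]
  vapply(seq_len(nsl), function(k) {
    if (axis == "xy") ssim_mean(a[, , k], b[, , k], sigma, k1, k2, L)
    else ssim_mean(a[, k, ], b[, k, ], sigma, k1, k2, L)
  }, numeric(1))
}

# mean SSIM of two 2D images with gaussian window
ssim_mean <- function(x, y, sigma = 1.5, k1 = 0.01, k2 = 0.03, L = 1) {
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  f <- function(m) gauss_blur(m, sigma)
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx * mx
  syy <- f(y * y) - my * my
  sxy <- f(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
       ((mx * mx + my * my + C1) * (sxx + syy + C2))
  mean(s)
}

#' Bilinear line profile through an image slice
#'
#' Samples image intensities along the segment from `start` to `end`
#' (matrix coordinates `(row, col)`, 1-based) with bilinear interpolation.
#'
#' @param slice 2D matrix.
#' @param start,end Endpoints `(row, col)`.
#' @param n_samples Number of samples (default 100).
#' @return Numeric vector of length `n_samples`.
#' @export
line_profile <- function(slice, start, end, n_samples = 100) {
  t <- seq(0, 1, length.out = n_samples)
  r <- start[1] + t * (end[1] - start[1])
  c <- start[2] + t * (end[2] - start[2])
  r <- pmin(pmax(r, 1), nrow(slice))
  c <- pmin(pmax(c, 1), ncol(slice))
  r0 <- pmin(floor(r), nrow(slice) - 1); c0 <- pmin(floor(c), ncol(slice) - 1)
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * slice[cbind(r0, c0)] +
    fr * (1 - fc) * slice[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * slice[cbind(r0, c0 + 1)] +
    fr * fc * slice[cbind(r0 + 1, c0 + 1)]
}

#' Triangulation-error study on the simulated phantom
#'
#' Reproduces the triangulation accuracy experiment: for every view the true
#' diaphragm-top position at the view's acquisition time is projected
#' exactly (i.e. a perfect tracking is assumed), the per-frame vertex
#' sequence is triangulated for each requested mode and angular offset, and
#' the per-frame 3D Euclidean and |z| errors against the moving ground truth
#' are summarized as mean and standard deviation.
#'
#' @param spec A [phantom_spec()].
#' @param geom Acquisition geometry.
#' @param offsets_deg Angular offsets to test (default `c(90, 30, 10)`).
#' @param modes Triangulation modes (default both).
#' @return Data frame with columns `mode`, `offset_deg`, `mean_3d`,
#'   `std_3d`, `mean_z`, `std_z` (mm).
#' @export
triangulation_error_study <- function(spec, geom,
                                      offsets_deg = c(90, 30, 10),
                                      modes = c("rectified_corrected",
                                                "standard")) {
  truth <- diaphragm_top_truth(spec, geom$timestamps)
  verts <- t(vapply(seq_len(geom$n_views), function(i)
    project_point(geom$matrices[[i]], truth[i, ]), numeric(2)))
  res <- expand.grid(mode = modes, offset_deg = offsets_deg,
                     stringsAsFactors = FALSE)
  res$mean_3d <- res$std_3d <- res$mean_z <- res$std_z <- NA_real_
  for (r in seq_len(nrow(res))) {
    pts <- triangulate_sequence(verts, geom, offset_deg = res$offset_deg[r],
                                mode = res$mode[r])
    d3 <- sqrt((pts$x - truth[, 1])^2 + (pts$y - truth[, 2])^2 +
               (pts$z - truth[, 3])^2)
    dz <- abs(pts$z - truth[, 3])
    res$mean_3d[r] <- mean(d3); res$std_3d[r] <- stats::sd(d3)
    res$mean_z[r] <- mean(dz); res$std_z[r] <- stats::sd(dz)
  }
  res[, c("mode", "offset_deg", "mean_3d", "std_3d", "mean_z", "std_z")]
}
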