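#' Extract the 1D respiration signal from triangulated points
#'
#' Respiratory organ motion is treated as a translation along the
#' superior-inferior (z) axis, so the per-view signal is
#' `r_i = z_ref - z_i`, the SI displacement of the diaphragm top relative to
#' a reference view (positive when the diaphragm has moved inferiorly, i.e.
#' toward inhale, relative to the reference).
#'
#' @param points3d Data frame from [triangulate_sequence()] (columns `x`,
#'   `y`, `z`), one row per view, no missing frames.
#' @param ref_index Reference view (1-based index, default 1 = scan start).
#' @param timestamps Optional per-view acquisition times (s).
#' @return A `respiration_signal`: list with `r` (mm, zero at the reference
#'   view), `z_ref`, `ref_index`, `timestamps`.
#' @export
extract_signal <- function(points3d, ref_index = 1L, timestamps = NULL) {
  z <- points3d$z
  if (!length(z)) stop("points3d is empty")
  if (anyNA(z)) stop("points3d has missing frames; fill them upstream")
  ref_index <- as.integer(ref_index)
  if (ref_index < 1L || ref_index > length(z)) stop("invalid ref_index")
  z_ref <- z[ref_index]
  structure(list(r = z_ref - z, z_ref = z_ref, ref_index = ref_index,
                 timestamps = timestamps),
            class = "respiration_signal")
}

#' @export
print.respiration_signal <- function(x, ...) {
  cat(sprintf("respiration_signal: %d views, range [%.3g, %.3g] mm (ref view %d)\n",
              length(x$r), min(x$r), max(x$r), x$ref_index))
  invisible(x)
}

#' @export
plot.respiration_signal <- function(x, ...) {
  t <- if (is.null(x$timestamps)) seq_along(x$r) - 1 else x$timestamps
  graphics::plot(t, x$r, type = "l",
                 xlab = if (is.null(x$timestamps)) "view" else "time (s)",
                 ylab = "SI displacement (mm)", ...)
  invisible(x)
}

#' Gaussian smoothing of a respiration signal
#'
#' Discrete gaussian convolution with a kernel normalized to sum 1 and
#' reflected boundaries, applied along the view index.
#'
#' @param signal A `respiration_signal`.
#' @param gauss_sigma_frames Kernel sigma in frames (default 2).
#' @return The smoothed `respiration_signal`.
#' @export
smooth_signal <- function(signal, gauss_sigma_frames = 2) {
  r <- signal$r
  if (gauss_sigma_frames <= 0) return(signal)
  rad <- max(1L, ceiling(4 * gauss_sigma_frames))
  k <- exp(-(-rad:rad)^2 / (2 * gauss_sigma_frames^2))
  k <- k / sum(k)
  n <- length(r)
  # reflect indices about the end points (period 2n - 2), valid for any rad
  refl <- function(i) {
    i <- abs(i - 1L) %% (2L * n - 2L)
    ifelse(i >= n, 2L * n - 2L - i, i) + 1L
  }
  rp <- r[refl((1L - rad):(n + rad))]
  sm <- vapply(seq_len(n),
               function(i) sum(k * rp[(i - 1L) + seq_along(k)]),
               numeric(1))
  signal$r <- sm
  signal
}

#' Linear diaphragm-to-target motion scale
#'
#' When the target region (e.g. the lung) moves less than the diaphragm, a
#' single linear scale relates the two. Given matched measurements of the
#' diaphragm-top z and the target z (e.g. from a set of static scans along
#' the breathing cycle), the scale is the least-squares slope of the target
#' displacement against the diaphragm displacement, both taken relative to
#' their first sample (regression through the origin).
#'
#' @param diaphragm_z,target_z Equal-length numeric vectors (mm), length
#'   >= 2; `diaphragm_z` must not be constant.
#' @return Dimensionless scale factor.
#' @export
estimate_linear_scale <- function(diaphragm_z, target_z) {
  if (length(diaphragm_z) != length(target_z) || length(diaphragm_z) < 2)
    stop("need equal-length inputs with at least 2 samples")
  x <- diaphragm_z - diaphragm_z[1]
  y <- target_z - target_z[1]
  if (all(x == 0)) stop("diaphragm positions are constant")
  sum(x * y) / sum(x * x)
}
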