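#' Decompose a finite projection matrix
#'
#' Splits `P = K [R | -R c]` into intrinsics `K` (upper triangular, positive
#' diagonal), rotation `R` and camera center `c` via RQ decomposition.
#'
#' @param P 3x4 projection matrix.
#' @return List with `K`, `R`, `center`.
#' @export
decompose_projection <- function(P) {
  M <- P[, 1:3]
  # RQ via QR of the row-reversed, transposed matrix
  E <- diag(3)[3:1, ]
  qrres <- qr(t(E %*% M))
  Q <- qr.Q(qrres); Rm <- qr.R(qrres)
  K <- E %*% t(Rm) %*% E
  R <- E %*% t(Q)
  # fix signs so K has a positive diagonal
  S <- diag(sign(diag(K)))
  K <- K %*% S
  R <- S %*% R
  if (det(R) < 0) { K <- -K; R <- -R }
  # normalize so K[3,3] = 1
  K <- K / K[3, 3]
  center <- -solve(M, P[, 4])
  list(K = K, R = R, center = center)
}

#' Epipolar rectification of a stereo pair
#'
#' Rectifies two pinhole cameras onto a common image plane so that epipolar
#' lines become parallel and horizontal: for a static 3D point, the rectified
#' v-coordinates in both views agree. Both rectified cameras share the
#' rotation whose x-axis is the baseline direction and the mean intrinsics of
#' the pair (skew removed).
#'
#' @param P_i,P_j 3x4 projection matrices of the pair.
#' @return A `rectified_pair`: list with new matrices `P1`, `P2` and 3x3
#'   pixel transforms `T1`, `T2` mapping original to rectified homogeneous
#'   detector coordinates.
#' @references Fusiello, Trucco, Verri: A compact algorithm for rectification
#'   of stereo pairs. Machine Vision and Applications 12 (2000).
#' @export
rectify_pair <- function(P_i, P_j) {
  d1 <- decompose_projection(P_i)
  d2 <- decompose_projection(P_j)
  baseline <- d2$center - d1$center
  if (sqrt(sum(baseline^2)) < 1e-9) stop("degenerate pair: coincident sources")
  v1 <- baseline
  v2 <- cross3(d1$R[3, ], v1)      # new y: orthogonal to old optical axis
  v3 <- cross3(v1, v2)             # new optical axis
  R <- rbind(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)), v3 / sqrt(sum(v3^2)))
  K <- (d1$K + d2$K) / 2
  K[1, 2] <- 0
  P1 <- K %*% cbind(R, -R %*% d1$center)
  P2 <- K %*% cbind(R, -R %*% d2$center)
  T1 <- (K %*% R) %*% solve(P_i[, 1:3])
  T2 <- (K %*% R) %*% solve(P_j[, 1:3])
  structure(list(P1 = P1, P2 = P2, T1 = T1, T2 = T2),
            class = "rectified_pair")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# apply a 3x3 homogeneous pixel transform to (u, v)
apply_pixel_transform <- function(Tm, uv) {
  h <- Tm %*% c(uv[1], uv[2], 1)
  c(h[1] / h[3], h[2] / h[3])
}

#' Motion correction of a rectified correspondence
#'
#' In a rectified pair any residual difference of the vertical coordinates of
#' corresponding points must be caused by motion between the two acquisition
#' times. The first point is kept as the reference; the second keeps its
#' horizontal coordinate and adopts the reference's vertical coordinate,
#' which removes the superior-inferior motion from the pair.
#'
#' @param g_ref Rectified reference point `(u, v)` (or homogeneous length 3).
#' @param g_partner Rectified partner point.
#' @return Corrected partner point as homogeneous `(u', v_ref, 1)`.
#' @export
motion_correct <- function(g_ref, g_partner) {
  c(g_partner[1], g_ref[2], 1)
}

#' Linear-Eigen two-view triangulation
#'
#' Solves the homogeneous linear system built from both projections for the
#' 3D point via the smallest right singular vector. The iterative variant
#' reweights each view's equations by the inverse of the point's current
#' depth estimate and repeats until the point moves less than `tol` or
#' `max_iter` is reached, which approximates minimizing the reprojection
#' error instead of the algebraic error.
#'
#' @param P_i,P_j Projection matrices.
#' @param g,g2 Detector points `(u, v)` (or homogeneous) in the two views.
#' @param iterative Use depth reweighting (default `TRUE`).
#' @param max_iter,tol Iteration controls.
#' @return Length-3 world point (mm).
#' @references Hartley & Sturm: Triangulation. CVIU 68 (1997).
#' @export
triangulate_linear_eigen <- function(P_i, P_j, g, g2, iterative = TRUE,
                                     max_iter = 10, tol = 1e-10) {
  A <- rbind(g[1] * P_i[3, ] - P_i[1, ],
             g[2] * P_i[3, ] - P_i[2, ],
             g2[1] * P_j[3, ] - P_j[1, ],
             g2[2] * P_j[3, ] - P_j[2, ])
  solve_h <- function(A) {
    sv <- svd(A)
    if (sv$d[3] < 1e-10 * sv$d[1])
      stop("degenerate triangulation: rays are (near) parallel")
    X <- sv$v[, 4]
    if (abs(X[4]) < 1e-14) stop("triangulated point at infinity")
    X / X[4]
  }
  X <- solve_h(A)
  if (iterative) {
    for (it in seq_len(max_iter)) {
      w1 <- sum(P_i[3, ] * X)
      w2 <- sum(P_j[3, ] * X)
      if (abs(w1) < 1e-12 || abs(w2) < 1e-12) break
      Aw <- A / c(w1, w1, w2, w2)
      Xn <- solve_h(Aw)
      if (sqrt(sum((Xn[1:3] - X[1:3])^2)) < tol) { X <- Xn; break }
      X <- Xn
    }
  }
  X[1:3]
}

#' Triangulate a tracked vertex sequence
#'
#' Pairs every frame `i` with the frame at a fixed angular offset (`i + k`
#' when available, else `i - k`), and triangulates the pair either with the
#' motion-corrected rectified scheme (`"rectified_corrected"`: rectify,
#' replace the partner's vertical coordinate by the reference's, iterative
#' Linear-Eigen) or as a plain static-scene triangulation (`"standard"`).
#' Frame `i` is always the reference of the motion correction, so the output
#' point is attributed to frame `i`'s acquisition time.
#'
#' @param vertices n x 2 matrix (or data frame) of per-frame detector
#'   vertices `(u, v)` in px.
#' @param geom The acquisition geometry.
#' @param offset_deg Angular offset between paired views (default 90,
#'   capped at the available range).
#' @param mode `"rectified_corrected"` (default) or `"standard"`.
#' @param iterative Use the iterative Linear-Eigen variant (default `TRUE`).
#' @return Data frame with columns `frame` (0-based), `x`, `y`, `z`,
#'   `partner_frame`.
#' @export
triangulate_sequence <- function(vertices, geom, offset_deg = 90,
                                 mode = c("rectified_corrected", "standard"),
                                 iterative = TRUE) {
  mode <- match.arg(mode)
  vertices <- as.matrix(vertices)
  n <- geom$n_views
  if (nrow(vertices) != n) stop("vertices must have one row per view")
  k <- as.integer(round(offset_deg / geom$increment))
  k <- min(max(k, 1L), n - 1L)
  out <- data.frame(frame = seq_len(n) - 1L, x = NA_real_, y = NA_real_,
                    z = NA_real_, partner_frame = NA_integer_)
  for (i in seq_len(n)) {
    j <- if (i + k <= n) i + k else i - k
    Pi <- geom$matrices[[i]]; Pj <- geom$matrices[[j]]
    gi <- vertices[i, 1:2]; gj <- vertices[j, 1:2]
    if (mode == "rectified_corrected") {
      rp <- rectify_pair(Pi, Pj)
      gri <- apply_pixel_transform(rp$T1, gi)
      grj <- apply_pixel_transform(rp$T2, gj)
      grj <- motion_correct(gri, grj)
      X <- triangulate_linear_eigen(rp$P1, rp$P2, gri, grj,
                                    iterative = iterative)
    } else {
      X <- triangulate_linear_eigen(Pi, Pj, gi, gj, iterative = iterative)
    }
    out$x[i] <- X[1]; out$y[i] <- X[2]; out$z[i] <- X[3]
    out$partner_frame[i] <- j - 1L
  }
  out
}
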