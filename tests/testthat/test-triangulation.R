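test_that("projection matrices decompose into K, R, center", {
  geom <- circular_trajectory(12, increment = 16, sod = 790, sdd = 1180)
  for (i in c(1, 5, 12)) {
    d <- decompose_projection(geom$matrices[[i]])
    expect_equal(d$center, geom$source_positions[i, ], tolerance = 1e-8)
    expect_equal(d$K[lower.tri(d$K)], rep(0, 3))
    expect_true(all(diag(d$K) > 0))
    expect_equal(t(d$R) %*% d$R, diag(3), tolerance = 1e-10)
    P2 <- d$K %*% cbind(d$R, -d$R %*% d$center)
    # equal up to global scale
    expect_equal(P2 / P2[3, 3], geom$matrices[[i]] / geom$matrices[[i]][3, 3],
                 tolerance = 1e-8)
  }
})

test_that("rectified static correspondences share the row coordinate", {
  geom <- circular_trajectory(200, increment = 1)
  set.seed(21)
  for (pair in 1:10) {
    i <- sample(100, 1); j <- i + sample(c(30, 60, 90), 1)
    rp <- rectify_pair(geom$matrices[[i]], geom$matrices[[j]])
    for (k in 1:10) {
      X <- runif(3, -90, 90)
      vi <- project_point(rp$P1, X)[["v"]]
      vj <- project_point(rp$P2, X)[["v"]]
      expect_lt(abs(vi - vj), 1e-6)
    }
  }
  expect_error(rectify_pair(geom$matrices[[1]], geom$matrices[[1]]),
               "coincident")
})

test_that("rectification transforms are consistent with the new cameras", {
  geom <- circular_trajectory(100, increment = 2)
  i <- 10; j <- 55
  rp <- rectify_pair(geom$matrices[[i]], geom$matrices[[j]])
  set.seed(5)
  for (k in 1:10) {
    X <- runif(3, -80, 80)
    # transforming the original projection equals projecting with the
    # rectified camera
    g <- project_point(geom$matrices[[i]], X)
    h <- rp$T1 %*% c(g, 1)
    expect_equal(c(h[1] / h[3], h[2] / h[3]),
                 unname(project_point(rp$P1, X)), tolerance = 1e-6)
    # triangulating transformed correspondences returns the original point
    g2 <- project_point(geom$matrices[[j]], X)
    h2 <- rp$T2 %*% c(g2, 1)
    Xr <- triangulate_linear_eigen(rp$P1, rp$P2,
                                   c(h[1] / h[3], h[2] / h[3]),
                                   c(h2[1] / h2[3], h2[2] / h2[3]))
    expect_equal(Xr, X, tolerance = 1e-6)
  }
})

test_that("motion correction replaces the partner's row coordinate", {
  expect_equal(motion_correct(c(10, 20, 1), c(30, 25, 1)), c(30, 20, 1))
  # static pair (equal rows): identity
  expect_equal(motion_correct(c(4, 7, 1), c(9, 7, 1)), c(9, 7, 1))
  # the corrected pair never has a row difference
  set.seed(2)
  for (k in 1:20) {
    a <- runif(3); b <- runif(3)
    expect_equal(motion_correct(a, b)[2], a[2])
  }
})

test_that("noiseless two-view triangulation is exact", {
  geom <- circular_trajectory(200, increment = 1)
  set.seed(31)
  for (k in 1:20) {
    X <- runif(3, -100, 100)
    i <- sample(100, 1); j <- i + sample(20:99, 1)
    Xh <- triangulate_linear_eigen(geom$matrices[[i]], geom$matrices[[j]],
                                   project_point(geom$matrices[[i]], X),
                                   project_point(geom$matrices[[j]], X))
    expect_lt(sqrt(sum((Xh - X)^2)), 1e-8)
  }
})

test_that("opposed views handle on-axis points gracefully", {
  geom <- circular_trajectory(181, increment = 1)
  # exactly collinear rays (point at the isocenter) are flagged degenerate
  X0 <- c(0, 0, 0)
  expect_error(
    triangulate_linear_eigen(geom$matrices[[1]], geom$matrices[[181]],
                             project_point(geom$matrices[[1]], X0),
                             project_point(geom$matrices[[181]], X0)),
    "degenerate|infinity")
  # an axis point off the source plane still has uniquely intersecting
  # (if poorly separated) rays and triangulates exactly
  X <- c(0, 0, 30)
  Xh <- triangulate_linear_eigen(geom$matrices[[1]], geom$matrices[[181]],
                                 project_point(geom$matrices[[1]], X),
                                 project_point(geom$matrices[[181]], X))
  expect_lt(sqrt(sum((Xh - X)^2)), 1e-6)
})

test_that("iterative reweighting does not hurt and can help under noise", {
  geom <- circular_trajectory(200, increment = 1)
  X <- c(60, 40, 30)
  i <- 5; j <- 35  # 30-degree offset: depth-asymmetric pair
  set.seed(7)
  e_it <- e_ni <- numeric(200)
  for (t in 1:200) {
    g1 <- project_point(geom$matrices[[i]], X) + rnorm(2, 0, 0.1)
    g2 <- project_point(geom$matrices[[j]], X) + rnorm(2, 0, 0.1)
    e_it[t] <- sqrt(sum((triangulate_linear_eigen(
      geom$matrices[[i]], geom$matrices[[j]], g1, g2,
      iterative = TRUE) - X)^2))
    e_ni[t] <- sqrt(sum((triangulate_linear_eigen(
      geom$matrices[[i]], geom$matrices[[j]], g1, g2,
      iterative = FALSE) - X)^2))
  }
  expect_lt(mean(e_it), mean(e_ni))
})

test_that("pure SI translation is eliminated by the corrected pipeline", {
  # the central claim: with exact correspondences of a point that moved
  # only along z between the two acquisitions, rectification plus row
  # replacement recovers the reference-time position
  geom <- circular_trajectory(200, increment = 1)
  set.seed(13)
  for (k in 1:20) {
    X <- c(runif(2, -80, 80), runif(1, -60, 60))
    dz <- runif(1, -12, 12)
    i <- sample(100, 1); j <- i + sample(c(10, 30, 90), 1)
    rp <- rectify_pair(geom$matrices[[i]], geom$matrices[[j]])
    gi <- project_point(rp$P1, X)
    gj <- project_point(rp$P2, X + c(0, 0, dz)) # partner sees the moved point
    gj <- motion_correct(gi, gj)
    Xh <- triangulate_linear_eigen(rp$P1, rp$P2, gi, gj)
    expect_lt(sqrt(sum((Xh - X)^2)), 0.05)
  }
})

test_that("sequence triangulation is exact for static scenes in both modes", {
  geom <- small_geom(n_views = 40, increment = 5)
  X <- c(-60, 0, -20)
  verts <- t(vapply(seq_len(40), function(i)
    project_point(geom$matrices[[i]], X), numeric(2)))
  for (mode in c("rectified_corrected", "standard")) {
    for (off in c(90, 45, 15)) {
      pts <- triangulate_sequence(verts, geom, offset_deg = off, mode = mode)
      err <- sqrt((pts$x - X[1])^2 + (pts$y - X[2])^2 + (pts$z - X[3])^2)
      expect_lt(max(err), 1e-6)
    }
  }
  # frames near the sequence end fall back to the backward partner
  pts <- triangulate_sequence(verts, geom, offset_deg = 90)
  k <- round(90 / 5)
  expect_equal(pts$partner_frame[40], 40 - 1 - k)
  expect_equal(pts$partner_frame[1], k)
})

test_that("corrected mode beats the standard mode on moving input", {
  ph <- phantom_spec()
  geom <- circular_trajectory(200, increment = 1)
  st <- triangulation_error_study(ph, geom, offsets_deg = 90)
  e_corr <- st$mean_3d[st$mode == "rectified_corrected"]
  e_std <- st$mean_3d[st$mode == "standard"]
  expect_gt(e_std, 10 * e_corr)

  # offset-direction symmetry: +k and -k pairing errors agree within 2x
  # (or both are at numerical zero)
  verts <- apex_vertices(ph, geom)
  truth <- diaphragm_top_truth(ph, geom$timestamps)
  pts <- triangulate_sequence(verts, geom, offset_deg = 90)
  err <- sqrt((pts$x - truth[, 1])^2 + (pts$y - truth[, 2])^2 +
              (pts$z - truth[, 3])^2)
  fwd <- mean(err[1:110])    # frames paired with i + k
  bwd <- mean(err[111:200])  # frames paired with i - k
  expect_true((fwd < 1e-6 && bwd < 1e-6) ||
              (fwd / bwd < 2 && bwd / fwd < 2))
})
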