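test_that("fit_sphere recovers exact spheres, including translated ones", {
  for (center in list(c(0, 0, 0), c(10, 20, 30), c(-4.5, 0.25, 7))) {
    fit <- fit_sphere(point_cloud(octahedron_points(center), "head"))
    expect_equal(fit$center, center, tolerance = 1e-12)
    expect_equal(fit$radius, 1, tolerance = 1e-12)
    expect_equal(fit$rms_residual, 0, tolerance = 1e-12)
    expect_equal(fit$n_used, 6L)
    expect_equal(fit$n_rejected, 0L)
  }
})

test_that("fit_sphere on noise-free data is exact under rigid motion", {
  pc <- sample_sphere_points(c(5, -3, 12), 14, 400, cap_angle = 120,
                             sigma = 0, seed = 21)
  for (s in 1:5) {
    m <- random_rigid_motion(40, 60, seed = 100 + s)
    fit <- fit_sphere(apply_transform(m, pc))
    expect_equal(fit$center, apply_transform(m, c(5, -3, 12)),
                 tolerance = 1e-9)
    expect_equal(fit$radius, 14, tolerance = 1e-9)
  }
})

test_that("fit_sphere matches the algebraic oracle on noisy data and is unbiased", {
  truth <- c(5, -3, 12)
  pc <- sample_sphere_points(truth, 14, 3000, sigma = 0.1, seed = 77)
  fit <- fit_sphere(pc)
  expect_lt(sqrt(sum((fit$center - truth)^2)), 0.02)
  oracle <- oracle_sphere_algebraic(pc$points)
  # with full spherical coverage and small noise the geometric and the
  # independent algebraic solutions agree closely
  expect_equal(fit$center, oracle$center, tolerance = 1e-3)
  expect_equal(fit$radius, oracle$radius, tolerance = 1e-3)

  # per-axis bias over 50 seeds on noisy hemispherical coverage
  errs <- t(vapply(1:50, function(s) {
    f <- fit_sphere(sample_sphere_points(truth, 14, 3000, cap_angle = 90,
                                         sigma = 0.1, seed = 1000 + s))
    f$center - truth
  }, numeric(3)))
  expect_true(all(abs(colMeans(errs)) < 0.02))
})

test_that("fit_sphere reports degeneracy for too few or coplanar points", {
  expect_error(fit_sphere(point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                                      "head")),
               class = "cupwear_degeneracy")
  coplanar <- cbind(matrix(rnorm(40), 20, 2), 0)
  expect_error(fit_sphere(point_cloud(coplanar, "head")),
               class = "cupwear_degeneracy")
})

test_that("fit_plane recovers exact planes up to sign", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  fit <- fit_plane(point_cloud(sq, "plane1"))
  expect_equal(abs(fit$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit$offset * sign(fit$normal[3]), 0, tolerance = 1e-12)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-12)

  # oblique plane x + y + z = 3
  u <- seq(-1, 1, length.out = 5)
  g <- expand.grid(a = u, b = u)
  pts <- cbind(1 + g$a, 1 + g$b, 1 - g$a - g$b)
  fit2 <- fit_plane(point_cloud(pts, "plane2"))
  expect_equal(fit2$normal, rep(1, 3) / sqrt(3), tolerance = 1e-12)
  expect_equal(fit2$offset, sqrt(3), tolerance = 1e-12)
})

test_that("fit_plane eliminates displaced outliers and matches the inlier oracle", {
  set.seed(42)
  inliers <- cbind(runif(500, -20, 20), runif(500, -20, 20),
                   2 + rnorm(500, 0, 0.15))
  outliers <- cbind(runif(50, -20, 20), runif(50, -20, 20),
                    2 + sample(c(-1, 1), 50, TRUE) * runif(50, 1, 3))
  pc <- point_cloud(rbind(inliers, outliers), "plane1")
  fit <- fit_plane(pc, filter_threshold = 0.5)
  expect_true(all(501:550 %in% fit$rejected_idx))
  expect_equal(abs(fit$offset), 2, tolerance = 0.02)
  expect_equal(fit$n_used + fit$n_rejected, 550L)

  oracle <- oracle_plane_tls(inliers)
  inlier_only <- setdiff(seq_len(500), fit$rejected_idx)
  # compare against the closed-form TLS on the inliers the fit retained
  refit_oracle <- oracle_plane_tls(rbind(inliers)[inlier_only, ])
  expect_equal(abs(sum(fit$normal * refit_oracle$normal)), 1, tolerance = 1e-9)
  expect_equal(abs(fit$offset), abs(refit_oracle$offset), tolerance = 1e-9)
  expect_equal(abs(sum(fit$normal * oracle$normal)), 1, tolerance = 1e-3)
})

test_that("fit_plane reports degeneracy for collinear points", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_plane(point_cloud(line, "plane1")),
               class = "cupwear_degeneracy")
})

test_that("filter_to_surface applies the strict more-than rule and preserves order", {
  pts <- rbind(c(0, 0, 0.1), c(0, 0, 0.5), c(0, 0, 0.6), c(0, 0, 0))
  pc <- point_cloud(pts, "plane1")
  out <- filter_to_surface(pc, function(p) abs(p[, 3]), threshold = 0.5)
  expect_equal(out$rejected_idx, 3L) # 0.6 rejected
  expect_equal(out$retained_idx, c(1L, 2L, 4L)) # 0.5 exactly is retained
  expect_equal(out$retained$points[, 3], c(0.1, 0.5, 0))
  # union is the input, conservation of points
  expect_equal(n_points(out$retained) + n_points(out$rejected), n_points(pc))
  # all residuals within threshold: no-op
  out2 <- filter_to_surface(pc, function(p) rep(0.4, nrow(p)), threshold = 0.5)
  expect_length(out2$rejected_idx, 0)
})

test_that("elimination loop reaches a fixed point and conserves points", {
  set.seed(8)
  pc <- sample_sphere_points(c(0, 0, 0), 10, 500, sigma = 0.15, seed = 8)
  # displace a known subset well beyond the threshold
  pc$points[1:25, ] <- pc$points[1:25, ] * 1.2
  fit <- fit_sphere(pc, filter_threshold = 0.5)
  expect_equal(fit$n_used + fit$n_rejected, 500L)
  # idempotence: refitting the retained points removes nothing further
  retained <- cloud_ <- pc
  retained$points <- pc$points[setdiff(1:500, fit$rejected_idx), ]
  fit2 <- fit_sphere(retained, filter_threshold = 0.5)
  expect_equal(fit2$n_rejected, 0L)
  expect_equal(fit2$center, fit$center, tolerance = 1e-9)
})

test_that("single-pass elimination is available via max_iterations = 1", {
  set.seed(9)
  pc <- sample_sphere_points(c(0, 0, 0), 10, 400, sigma = 0, seed = 9)
  pc$points[1:20, ] <- pc$points[1:20, ] * 1.15 # 1.5 mm outliers
  f1 <- fit_sphere(pc, filter_threshold = 0.5, max_iterations = 1)
  expect_equal(f1$n_elimination_passes, 1L)
  expect_equal(sort(f1$rejected_idx), 1:20)
  expect_equal(f1$radius, 10, tolerance = 1e-9)
})

test_that("build_cup_frame is orthonormal with z toward the opening", {
  s <- fit_sphere(sample_sphere_points(c(0, 0, 0), 27, 500,
                                       cap_direction = c(0, 0, -1),
                                       cap_angle = 90, sigma = 0, seed = 31,
                                       label = "cup_outer"))
  mk_plane <- function(normal, center, label) {
    B <- cupwear:::basis_from_direction(normal)
    ang <- seq(0, 2 * pi, length.out = 81)[-81]
    r <- rep(c(16, 20), length.out = 80)
    pts <- sweep(cbind(r * cos(ang), r * sin(ang), 0) %*% t(B), 2L, -center)
    fit_plane(point_cloud(pts, label))
  }
  n2 <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  p1 <- mk_plane(c(0, 0, 1), c(0, 0, 0), "plane1")
  p2 <- mk_plane(n2 / sqrt(sum(n2^2)), c(0, 0, 2), "plane2")
  fr <- build_cup_frame(s, p1, p2)
  R <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(cupwear:::cross3(fr$x_axis, fr$y_axis), fr$z_axis,
               tolerance = 1e-9)
  # z within 5 degrees of the mean opening normal, pointing away from dome
  expect_lt(acos(sum(fr$z_axis * c(0, 0, 1))) * 180 / pi, 5 + 1e-9)
})

test_that("build_cup_frame is rigid-motion equivariant", {
  spec <- small_spec(noise_sigma = 0, reposition = FALSE, seed = 12)
  pair <- generate_scan_pair(spec)
  scan <- pair$pre
  base <- cupwear:::ct_fit_scan(scan, 0.5, 10L)
  for (s in 1:5) {
    m <- random_rigid_motion(30, 45, seed = 500 + s)
    moved <- cupwear:::ct_fit_scan(rigid_move_scan(scan, m), 0.5, 10L)
    expect_equal(moved$frame$origin, apply_transform(m, base$frame$origin),
                 tolerance = 1e-8)
    for (ax in c("x_axis", "y_axis", "z_axis")) {
      expect_equal(moved$frame[[ax]], drop(m$rotation %*% base$frame[[ax]]),
                   tolerance = 1e-8)
    }
  }
  # pure translation moves the origin and leaves axes unchanged
  tr <- rigid_transform(diag(3), c(5, -7, 11))
  moved <- cupwear:::ct_fit_scan(rigid_move_scan(scan, tr), 0.5, 10L)
  expect_equal(moved$frame$origin, base$frame$origin + c(5, -7, 11),
               tolerance = 1e-8)
  expect_equal(moved$frame$x_axis, base$frame$x_axis, tolerance = 1e-9)
})

test_that("frame_transform preserves frame-relative coordinates and round-trips", {
  mk_frame <- function(seed) {
    m <- random_rigid_motion(20, 180, seed = seed)
    cup_frame(m$translation, m$rotation[, 1], m$rotation[, 2], m$rotation[, 3])
  }
  f1 <- mk_frame(1); f2 <- mk_frame(2)
  # identity when frames coincide
  id <- frame_transform(f1, f1)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)
  # 90 degree rotation about z between frames is the known permutation
  fz <- cup_frame(c(0, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  fw <- cup_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tz <- frame_transform(fz, fw)
  expect_equal(tz$rotation,
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3), tolerance = 1e-12)
  # frame-relative coordinates are preserved for random points
  set.seed(4)
  pts <- matrix(rnorm(300, sd = 30), 100, 3)
  tf <- frame_transform(f1, f2)
  mapped <- apply_transform(tf, pts)
  expect_equal(world_to_frame(f2, mapped), world_to_frame(f1, pts),
               tolerance = 1e-9)
  # composing with the inverse gives the identity
  back <- compose_transforms(frame_transform(f2, f1), tf)
  expect_lt(max(abs(apply_transform(back, pts) - pts)), 1e-9)
})

test_that("rigid transforms preserve pairwise distances", {
  set.seed(5)
  pts <- matrix(rnorm(30, sd = 10), 10, 3)
  for (s in 1:20) {
    m <- random_rigid_motion(50, 30, seed = s)
    expect_equal(abs(det(m$rotation)), 1, tolerance = 1e-9)
    expect_equal(as.matrix(dist(apply_transform(m, pts))),
                 as.matrix(dist(pts)), tolerance = 1e-9)
  }
})
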