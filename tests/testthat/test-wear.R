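test_that("wear_angles follows the standard spherical convention", {
  cases <- list(list(v = c(0, 0, 1), theta = 0, phi = 0),
                list(v = c(1, 0, 0), theta = 90, phi = 0),
                list(v = c(0, 1, 0), theta = 90, phi = 90),
                list(v = c(-1, 0, 0), theta = 90, phi = 180),
                list(v = c(0, -1, 0), theta = 90, phi = -90),
                list(v = c(0, 0, -1), theta = 180, phi = 0))
  for (cs in cases) {
    a <- wear_angles(cs$v)
    expect_true(a$defined)
    expect_equal(a$theta, cs$theta, tolerance = 1e-12)
    expect_equal(a$phi, cs$phi, tolerance = 1e-12)
  }
  z <- wear_angles(c(0, 0, 0))
  expect_false(z$defined)
  expect_equal(c(z$theta, z$phi), c(0, 0))
})

test_that("wear_angles round-trips through spherical-to-Cartesian", {
  set.seed(13)
  for (i in 1:50) {
    v <- rnorm(3)
    a <- wear_angles(v)
    expect_true(a$theta >= 0 && a$theta <= 180)
    expect_true(a$phi > -180 && a$phi <= 180)
    th <- a$theta * pi / 180; ph <- a$phi * pi / 180
    back <- sqrt(sum(v^2)) * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    b <- wear_angles(back)
    expect_equal(b$theta, a$theta, tolerance = 1e-9)
    expect_equal(b$phi, a$phi, tolerance = 1e-9)
    expect_equal(back, v, tolerance = 1e-9)
  }
})

test_that("ct_wear of a rigidly moved copy of the same scan is zero", {
  pair <- generate_scan_pair(small_spec(wear_vector_true = c(0, 0, 0),
                                        noise_sigma = 0, reposition = FALSE,
                                        seed = 2))
  m <- random_rigid_motion(40, 25, seed = 3)
  post <- rigid_move_scan(pair$pre, m)
  post$scan_id <- "pre"
  w <- ct_wear(pair$pre, post)
  expect_lt(w$linear_wear, 1e-8)
  expect_false(w$angles_defined && w$linear_wear > 1e-8)
})

test_that("ct_wear recovers a known wear vector within tolerance", {
  pair <- generate_scan_pair(phantom_spec(wear_vector_true = c(0.5, 0, 0),
                                          noise_sigma = 0.1, seed = 42))
  w <- ct_wear(pair$pre, pair$post)
  expect_equal(w$linear_wear, 0.5, tolerance = 0.05 / 0.5)
  expect_lt(abs(w$linear_wear - 0.5), 0.05)
  expect_lt(abs(w$theta - 90), 5)
  expect_equal(w$method, "CT")
  expect_equal(w$linear_wear, sqrt(sum(w$wear_vector^2)), tolerance = 1e-12)
  # diagnostics carry per-surface fit summaries
  expect_named(w$diagnostics, c("pre", "post"))
  expect_equal(w$diagnostics$pre$head$n_used +
                 w$diagnostics$pre$head$n_rejected, 3750)
})

test_that("ct_wear is invariant to an extra rigid motion of one scan", {
  pair <- generate_scan_pair(small_spec(wear_vector_true = c(0.3, -0.2, 0.4),
                                        noise_sigma = 0.1, seed = 6))
  w0 <- ct_wear(pair$pre, pair$post)
  for (s in 1:20) {
    m <- random_rigid_motion(50, 30, seed = 700 + s)
    w <- ct_wear(pair$pre, rigid_move_scan(pair$post, m))
    expect_lt(abs(w$linear_wear - w0$linear_wear), 1e-6)
    expect_lt(max(abs(w$wear_vector - w0$wear_vector)), 1e-6)
  }
})

test_that("ct_wear names the offending surface and scan on degeneracy", {
  pair <- generate_scan_pair(small_spec(noise_sigma = 0, seed = 14))
  bad <- pair$post
  bad$head <- point_cloud(cbind(rnorm(20), rnorm(20), 0), "head",
                          scan_id = "post")
  err <- tryCatch(ct_wear(pair$pre, bad), cupwear_degeneracy = identity)
  expect_s3_class(err, "cupwear_degeneracy")
  expect_match(conditionMessage(err), "head")
  expect_match(conditionMessage(err), "post")
})

test_that("split_hemispheres partitions by frame x sign and conserves points", {
  frame <- cup_frame(c(1, 2, 3), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  set.seed(15)
  pts <- sweep(matrix(rnorm(900), 300, 3), 2L, -c(1, 2, 3))
  pc <- point_cloud(pts, "cup_inner")
  halves <- split_hemispheres(pc, frame)
  census <- (pts[, 1] - 1) >= 0
  expect_equal(halves$worn_idx, which(census))
  expect_equal(n_points(halves$worn_side) + n_points(halves$unworn_side), 300)
  # worn_sign flips the assignment; mirrored inputs swap sides
  flipped <- split_hemispheres(pc, frame, worn_sign = -1)
  expect_equal(flipped$worn_idx, halves$unworn_idx)
  mirrored <- pc
  mirrored$points[, 1] <- 2 - mirrored$points[, 1] # reflect about frame x = 0
  halves_m <- split_hemispheres(mirrored, frame)
  expect_equal(n_points(halves_m$worn_side),
               sum((2 - pts[, 1] - 1) >= 0))
  # all points on one side leaves the other empty
  right <- point_cloud(sweep(cbind(abs(rnorm(50)) + 0.1, rnorm(50), rnorm(50)),
                             2L, -c(1, 2, 3)), "cup_inner")
  expect_equal(n_points(split_hemispheres(right, frame)$unworn_side), 0)
})

test_that("cmm_wear is zero for identical scans and recovers displacement", {
  spec <- small_spec(wear_vector_true = c(0, 0, 0), include_inner = TRUE,
                     noise_sigma = 0, reposition = FALSE, seed = 16)
  pair <- generate_scan_pair(spec)
  planes <- list(plane1 = pair$pre$plane1, plane2 = pair$pre$plane2)
  w0 <- cmm_wear(pair$pre$cup_inner, pair$pre$cup_inner, planes, planes)
  expect_lt(w0$linear_wear, 1e-9)

  spec2 <- phantom_spec(wear_vector_true = c(0.3, 0, 0.2),
                        include_inner = TRUE, noise_sigma = 0.05,
                        seed = 17)
  pair2 <- generate_scan_pair(spec2)
  w <- cmm_wear(pair2$pre$cup_inner, pair2$post$cup_inner,
                list(plane1 = pair2$pre$plane1, plane2 = pair2$pre$plane2),
                list(plane1 = pair2$post$plane1, plane2 = pair2$post$plane2))
  expect_equal(w$method, "CMM")
  expect_lt(abs(w$linear_wear - sqrt(0.09 + 0.04)), 0.05)
})

test_that("cmm_wear reports degeneracy when a hemisphere is starved", {
  spec <- small_spec(include_inner = TRUE, noise_sigma = 0,
                     reposition = FALSE, cup_inclination = 0, seed = 18)
  pair <- generate_scan_pair(spec)
  planes <- list(plane1 = pair$pre$plane1, plane2 = pair$pre$plane2)
  # collapse the inner cloud onto one hemisphere (canonical frame: x < 0)
  inner <- pair$pre$cup_inner
  inner$points <- inner$points[inner$points[, 1] < -1, , drop = FALSE]
  expect_error(cmm_wear(inner, inner, planes, planes),
               class = "cupwear_degeneracy")
})

test_that("mass-to-volume conversion uses the polyethylene density", {
  expect_equal(wear_volume_from_mass(0), 0)
  expect_equal(wear_volume_from_mass(935), 1000)
  expect_equal(round(wear_volume_from_mass(200), 2), 213.90)
  expect_equal(wear_volume_from_mass(-10), -10 / 0.935) # soak gain
  expect_equal(wear_volume_from_mass(100, density_mg_mm3 = 1), 100)
  expect_error(wear_volume_from_mass(1, density_mg_mm3 = 0),
               class = "cupwear_parse")
})
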