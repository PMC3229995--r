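# shared fixtures built in code

# six exact points of the unit octahedron: a perfect unit sphere
octahedron_points <- function(center = c(0, 0, 0), radius = 1) {
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  sweep(base * radius, 2L, -center)
}

# a quick low-count phantom spec for unit tests (acceptance tests use the
# full default digitization counts)
small_spec <- function(...) {
  phantom_spec(n_cup = 800, n_head = 1000, n_plane = 200, n_inner = 800, ...)
}

rigid_move_scan <- function(scan, motion) {
  for (nm in intersect(names(scan), SURFACE_LABELS)) {
    scan[[nm]] <- apply_transform(motion, scan[[nm]])
  }
  scan
}

# independent closed-form algebraic sphere fit used as an oracle
oracle_sphere_algebraic <- function(pts) {
  A <- cbind(2 * pts, 1)
  beta <- qr.coef(qr(A), rowSums(pts^2))
  center <- unname(beta[1:3])
  list(center = center, radius = sqrt(unname(beta[4]) + sum(center^2)))
}

# independent closed-form total-least-squares plane (no outlier handling)
oracle_plane_tls <- function(pts) {
  m <- colMeans(pts)
  v <- svd(sweep(pts, 2L, m), nu = 0)$v[, 3]
  if (v[which.max(abs(v))] < 0) v <- -v
  list(normal = v, offset = sum(v * m))
}
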