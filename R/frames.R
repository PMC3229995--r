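# --- cup coordinate frames and rigid transforms ---------------------------

#' Construct a cup frame from explicit axes
#'
#' Low-level constructor validating orthonormality (to 1e-9) and
#' right-handedness (`x × y = z`). Most callers use [build_cup_frame].
#'
#' @param origin 3-vector, mm
#' @param x_axis,y_axis,z_axis unit 3-vectors forming a right-handed basis
#' @return object of class `cup_frame`
#' @export
cup_frame <- function(origin, x_axis, y_axis, z_axis) {
  R <- cbind(x = x_axis, y = y_axis, z = z_axis)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    abort_degenerate("cup frame axes are not orthonormal to 1e-9")
  }
  if (max(abs(cross3(x_axis, y_axis) - z_axis)) > 1e-9) {
    abort_degenerate("cup frame is not right-handed (x cross y != z)")
  }
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "cup_frame")
}

frame_basis <- function(frame) cbind(frame$x_axis, frame$y_axis, frame$z_axis)

#' Build the cup-anchored coordinate frame
#'
#' The frame is anchored on the fitted cup sphere and the two opening-face
#' planes: the origin is the cup-sphere center; the z axis is the normalized
#' mean of the two (co-oriented) plane normals, flipped to point away from
#' the cup dome; the x axis is the direction of the planes' intersection
#' line projected orthogonal to z; y completes the right-handed triad.
#'
#' The x-axis sign is inherited from `n1 × n2` after co-orienting the
#' normals, which is deterministic and rigid-motion equivariant (a joint
#' sign flip of both normals cancels in the cross product). When the two
#' planes are parallel within `parallel_tol_deg` the intersection line is
#' undefined; if `fallback_azimuth` is `TRUE` the world +x axis projected
#' into the opening plane is used instead — an arbitrary but deterministic
#' azimuth reference, adequate only when scans are not repositioned —
#' otherwise a degeneracy error is raised.
#'
#' @param cup_sphere a [sphere_fit] of the cup surface (its `centroid`
#'   marks the dome side)
#' @param plane1,plane2 [fit_plane] results for the two opening faces
#' @param dome_point a point on the dome side of the opening plane, used to
#'   orient z away from the dome; defaults to the centroid of the cup-sphere
#'   fit's retained points
#' @param parallel_tol_deg angle below which the planes count as parallel
#'   (default 1 degree)
#' @param fallback_azimuth use the world-x fallback for parallel planes?
#' @return a [cup_frame]
#' @export
build_cup_frame <- function(cup_sphere, plane1, plane2,
                            dome_point = cup_sphere$centroid,
                            parallel_tol_deg = 1, fallback_azimuth = TRUE) {
  stopifnot(inherits(cup_sphere, "sphere_fit"),
            inherits(plane1, "plane_fit"), inherits(plane2, "plane_fit"))
  n1 <- plane1$normal
  n2 <- plane2$normal
  if (sum(n1 * n2) < 0) n2 <- -n2
  z <- normalize(n1 + n2)
  origin <- cup_sphere$center
  if (!is.null(dome_point) && sum(z * (dome_point - origin)) > 0) z <- -z

  cr <- cross3(n1, n2)
  parallel <- vnorm(cr) < sin(parallel_tol_deg * pi / 180)
  if (parallel) {
    if (!fallback_azimuth) {
      abort_degenerate("opening-face planes are parallel within ",
                       parallel_tol_deg, " deg: no azimuth reference")
    }
    x_raw <- c(1, 0, 0) - z[1] * z
    if (vnorm(x_raw) < 1e-6) x_raw <- c(0, 1, 0) - z[2] * z
  } else {
    x_raw <- cr - sum(cr * z) * z
  }
  x <- normalize(x_raw)
  y <- cross3(z, x)
  cup_frame(origin, x, y, z)
}

#' Express world points in a frame / map frame coordinates back to world
#'
#' `world_to_frame` returns the coordinates of world points relative to the
#' frame (origin subtracted, projected on the axes); `frame_to_world`
#' inverts it.
#'
#' @param frame a [cup_frame]
#' @param pts n x 3 matrix or 3-vector
#' @return matrix (or vector) of the same shape
#' @export
world_to_frame <- function(frame, pts) {
  v <- is.null(dim(pts))
  p <- if (v) matrix(pts, 1L) else as.matrix(pts)
  out <- sweep(p, 2L, frame$origin) %*% frame_basis(frame)
  if (v) drop(out) else out
}

#' @rdname world_to_frame
#' @export
frame_to_world <- function(frame, pts) {
  v <- is.null(dim(pts))
  p <- if (v) matrix(pts, 1L) else as.matrix(pts)
  out <- sweep(p %*% t(frame_basis(frame)), 2L, -frame$origin)
  if (v) drop(out) else out
}

#' Create a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation 3-vector, mm
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    abort_degenerate("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rigid transform mapping one cup frame onto another
#'
#' Returns the rigid transform that takes a point expressed in the world of
#' `from_frame` to the point with the same frame-relative coordinates in the
#' world of `to_frame`; composing a frame's transform with its inverse gives
#' the identity.
#'
#' @param from_frame,to_frame [cup_frame] objects
#' @return a [rigid_transform]
#' @export
frame_transform <- function(from_frame, to_frame) {
  Rf <- frame_basis(from_frame)
  Rt <- frame_basis(to_frame)
  R <- Rt %*% t(Rf)
  t <- to_frame$origin - drop(R %*% from_frame$origin)
  rigid_transform(R, t)
}

#' Apply a rigid transform to points or a point cloud
#'
#' @param transform a [rigid_transform]
#' @param x n x 3 matrix, 3-vector, or [point_cloud]
#' @return object of the same kind as `x`
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "point_cloud")) {
    x$points <- apply_transform(transform, x$points)
    dimnames(x$points) <- list(NULL, c("x", "y", "z"))
    return(x)
  }
  v <- is.null(dim(x))
  p <- if (v) matrix(x, 1L) else as.matrix(x)
  out <- sweep(p %*% t(transform$rotation), 2L, -transform$translation)
  if (v) drop(out) else out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform]
#' @return the inverse [rigid_transform]
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform] objects
#' @return the composite [rigid_transform]
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (not necessarily
#' unit) `axis`, right-handed.
#'
#' @param axis 3-vector
#' @param angle_deg angle in degrees
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  if (angle_deg == 0) return(diag(3))
  u <- normalize(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
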