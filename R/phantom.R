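# --- synthetic phantom ----------------------------------------------------
#
# Emulates a hip-phantom validation study: a UHMWPE cup with a metal-meshed
# outer surface and a 28 mm head mounted at 45 deg inclination, digitized as
# labelled point clouds before and after a known head displacement (the true
# wear vector), with Gaussian surface noise, metal-artifact outliers and a
# deliberate rigid repositioning between the two scans.

#' Specify a synthetic phantom
#'
#' Parameters of the synthetic pre-/post-wear scan pair. Defaults mirror the
#' phantom bench conditions the package is validated against: 28 mm head,
#' 48-64 mm cup outer diameter (default 54 mm), 0.51 mm diametral head-cup
#' clearance, 45 deg cup inclination, mid-range digitization counts
#' (cup 2500 of 1000-4000; head 3750 of 2500-5000; planes 500 of 200-800),
#' 0.1 mm Gaussian surface noise, and rigid repositioning between scans.
#'
#' @param cup_outer_diameter mm, in `[48, 64]` by default validation
#' @param head_diameter mm (default 28)
#' @param clearance diametral head-cup clearance in mm (default 0.51)
#' @param cup_inclination cup inclination in degrees (default 45)
#' @param wear_vector_true 3-vector, the true head displacement in cup-frame
#'   coordinates (mm)
#' @param noise_sigma Gaussian surface noise SD along the local surface
#'   normal, mm
#' @param outlier_fraction fraction of points per cloud displaced as
#'   metal-artifact outliers, in `[0, 1)`
#' @param outlier_min_offset minimum outward displacement of an outlier, mm
#'   (must exceed the intended filter threshold to be detectable)
#' @param n_cup,n_head,n_plane digitization counts per surface
#' @param reposition apply an independent random rigid motion to each scan?
#' @param seed integer seed; the pair is bit-for-bit reproducible from it
#' @param plane_separation distance between the two opening faces, mm
#' @param plane2_tilt tilt of the second opening face in degrees (default
#'   10): the two faces of the cup rim are chamfer-like, not coplanar, and
#'   the tilt is what makes the in-plane azimuth geometrically identifiable
#'   (with `plane2_tilt = 0`, parallel faces, the azimuth falls back to an
#'   arbitrary world-derived reference and only the wear magnitude along z
#'   survives repositioning)
#' @param mesh_sigma_multiplier extra roughness factor applied to the
#'   metal-meshed outer cup surface noise (default 1.5)
#' @param voxel_grid optional slice-reconstruction increment in mm; when
#'   given, z coordinates are snapped to this grid (off by default)
#' @param max_translation,max_rotation repositioning bounds, mm / degrees
#' @param include_inner also generate the inner articulating surface (for
#'   the CMM-style variant)?
#' @param n_inner digitization count for the inner surface
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(cup_outer_diameter = 54, head_diameter = 28,
                         clearance = 0.51, cup_inclination = 45,
                         wear_vector_true = c(0, 0, 0), noise_sigma = 0.1,
                         outlier_fraction = 0, outlier_min_offset = 1,
                         n_cup = 2500, n_head = 3750, n_plane = 500,
                         reposition = TRUE, seed = 1L,
                         plane_separation = 2, plane2_tilt = 10,
                         mesh_sigma_multiplier = 1.5, voxel_grid = NULL,
                         max_translation = 50, max_rotation = 30,
                         include_inner = FALSE, n_inner = 2000) {
  if (cup_outer_diameter <= 0 || head_diameter <= 0) {
    abort_parse("diameters must be positive")
  }
  if (clearance < 0) abort_parse("clearance must be nonnegative")
  if (head_diameter + clearance >= cup_outer_diameter) {
    abort_parse("head plus clearance must fit inside the cup outer diameter")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    abort_parse("outlier_fraction must be in [0, 1)")
  }
  if (noise_sigma < 0) abort_parse("noise_sigma must be nonnegative")
  wear_vector_true <- as.numeric(wear_vector_true)
  if (length(wear_vector_true) != 3L || !all(is.finite(wear_vector_true))) {
    abort_parse("wear_vector_true must be a finite 3-vector")
  }
  if (vnorm(wear_vector_true) > (cup_outer_diameter - head_diameter) / 2) {
    abort_parse("wear vector larger than the cup wall: infeasible phantom")
  }
  if (n_cup < 4 || n_head < 4 || n_plane < 3) {
    abort_parse("point counts too small to support fitting")
  }
  structure(list(cup_outer_diameter = cup_outer_diameter,
                 head_diameter = head_diameter, clearance = clearance,
                 cup_inclination = cup_inclination,
                 wear_vector_true = wear_vector_true,
                 noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction,
                 outlier_min_offset = outlier_min_offset,
                 n_cup = n_cup, n_head = n_head, n_plane = n_plane,
                 reposition = reposition, seed = as.integer(seed),
                 plane_separation = plane_separation,
                 plane2_tilt = plane2_tilt,
                 mesh_sigma_multiplier = mesh_sigma_multiplier,
                 voxel_grid = voxel_grid,
                 max_translation = max_translation,
                 max_rotation = max_rotation,
                 include_inner = include_inner, n_inner = n_inner),
            class = "phantom_spec")
}

# orthonormal basis with w as third column
basis_from_direction <- function(w) {
  w <- normalize(w)
  seed_axis <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(seed_axis - sum(seed_axis * w) * w)
  v <- cross3(w, u)
  cbind(u, v, w)
}

#' Sample points on a spherical cap
#'
#' Uniform-by-area sampling on the cap of half-angle `cap_angle` around
#' `cap_direction`, with i.i.d. Gaussian radial noise of SD `sigma` applied
#' along the surface normal. Deterministic for a given seed.
#'
#' @param center sphere center, 3-vector mm
#' @param radius sphere radius, mm
#' @param n number of points
#' @param cap_direction axis of the cap (default +z)
#' @param cap_angle cap half-angle in degrees, in `(0, 180]`
#' @param sigma radial noise SD, mm
#' @param seed optional integer seed (RNG state is restored afterwards)
#' @param label,scan_id metadata for the returned [point_cloud]
#' @return a [point_cloud]
#' @export
sample_sphere_points <- function(center, radius, n,
                                 cap_direction = c(0, 0, 1), cap_angle = 180,
                                 sigma = 0, seed = NULL,
                                 label = "head", scan_id = "scan") {
  stopifnot(n >= 1, cap_angle > 0, cap_angle <= 180, radius > 0, sigma >= 0)
  with_seed(seed, {
    cosmin <- cos(cap_angle * pi / 180)
    cost <- runif(n, cosmin, 1)
    sint <- sqrt(pmax(0, 1 - cost^2))
    az <- runif(n, 0, 2 * pi)
    B <- basis_from_direction(cap_direction)
    dirs <- cbind(sint * cos(az), sint * sin(az), cost) %*% t(B)
    r <- radius + if (sigma > 0) rnorm(n, 0, sigma) else 0
    pts <- sweep(dirs * r, 2L, -as.numeric(center))
    point_cloud(pts, label = label, scan_id = scan_id)
  })
}

# annulus in the plane through `center` with normal `normal`;
# radii sampled uniform-by-area in [r_inner, r_outer]
sample_annulus_points <- function(center, normal, r_inner, r_outer, n,
                                  sigma = 0, label = "plane1",
                                  scan_id = "scan") {
  B <- basis_from_direction(normal)
  r <- sqrt(runif(n, r_inner^2, r_outer^2))
  az <- runif(n, 0, 2 * pi)
  inplane <- cbind(r * cos(az), r * sin(az), 0) %*% t(B)
  off <- if (sigma > 0) rnorm(n, 0, sigma) else rep(0, n)
  pts <- sweep(inplane + outer(off, normalize(normal)), 2L, -as.numeric(center))
  point_cloud(pts, label = label, scan_id = scan_id)
}

#' Draw a random rigid motion
#'
#' Uniformly random rotation axis, rotation angle uniform in
#' `[0, max_rotation]` degrees, and translation components uniform in
#' `[-max_translation, max_translation]` mm. With both bounds zero the
#' identity is returned. Deterministic per seed.
#'
#' @param max_translation bound on each translation component, mm
#' @param max_rotation bound on the rotation angle, degrees
#' @param seed optional integer seed
#' @return a [rigid_transform]
#' @export
random_rigid_motion <- function(max_translation = 50, max_rotation = 30,
                                seed = NULL) {
  stopifnot(max_translation >= 0, max_rotation >= 0)
  with_seed(seed, {
    ax <- rnorm(3)
    while (vnorm(ax) < 1e-8) ax <- rnorm(3)
    ang <- runif(1, 0, max_rotation)
    tr <- runif(3, -max_translation, max_translation)
    rigid_transform(rotation_about_axis(ax, ang), tr)
  })
}

# displace a fraction of points outward along `normal_fn(points)` by at
# least `min_offset`; returns the modified cloud and the outlier indices
inject_outliers <- function(cloud, fraction, min_offset, normal_fn) {
  n <- n_points(cloud)
  k <- floor(n * fraction)
  if (k < 1L) return(list(cloud = cloud, idx = integer(0)))
  idx <- sort(sample.int(n, k))
  nrm <- normal_fn(cloud$points[idx, , drop = FALSE])
  mag <- min_offset * (1 + runif(k, 0, 0.5))
  cloud$points[idx, ] <- cloud$points[idx, ] + nrm * mag
  list(cloud = cloud, idx = idx)
}

#' Generate a synthetic pre-/post-wear scan pair with known truth
#'
#' Builds the phantom in a canonical cup frame (origin at the cup center,
#' dome toward -z, opening toward +z): the outer cup hemisphere, the head
#' resting half the clearance toward the dome, the two opening-face annuli
#' (the second tilted by `plane2_tilt`), and optionally the inner surface.
#' The post scan repeats the geometry with the head center (and, for the
#' inner surface, the worn hemisphere) displaced by `wear_vector_true`.
#' Both scans are rotated to the mounting inclination and, when
#' `reposition` is `TRUE`, each is subjected to an independent random rigid
#' motion — the software must undo this, as a scanner cannot guarantee
#' identical positioning. Noise and artifact outliers are applied per
#' surface; the returned truth records the injected wear and the outlier
#' bookkeeping.
#'
#' @param spec a [phantom_spec]
#' @return list with `pre` and `post` [scan_data] and `truth`, a
#'   `wear_result` whose `diagnostics` carry `outlier_idx` (per scan and
#'   surface) and the generating `spec`
#' @examples
#' pair <- generate_scan_pair(phantom_spec(wear_vector_true = c(0.5, 0, 0),
#'                                         seed = 7))
#' pair$truth$linear_wear
#' @export
generate_scan_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    R_cup <- spec$cup_outer_diameter / 2
    r_head <- spec$head_diameter / 2
    r_inner <- (spec$head_diameter + spec$clearance) / 2
    head_center_pre <- c(0, 0, -spec$clearance / 2)
    head_center_post <- head_center_pre + spec$wear_vector_true
    tilt <- spec$plane2_tilt * pi / 180
    # tilting plane2's normal toward -y puts the frame x axis (the projected
    # n1 x n2 direction) on the canonical +x axis
    n2 <- c(0, -sin(tilt), cos(tilt))
    sig <- spec$noise_sigma
    R_incl <- rotation_about_axis(c(0, 1, 0), spec$cup_inclination)

    make_scan <- function(scan_id, head_center) {
      clouds <- list(
        cup_outer = sample_sphere_points(c(0, 0, 0), R_cup, spec$n_cup,
                                         cap_direction = c(0, 0, -1),
                                         cap_angle = 90,
                                         sigma = sig * spec$mesh_sigma_multiplier,
                                         label = "cup_outer", scan_id = scan_id),
        head = sample_sphere_points(head_center, r_head, spec$n_head,
                                    cap_direction = c(0, 0, 1), cap_angle = 90,
                                    sigma = sig, label = "head",
                                    scan_id = scan_id),
        plane1 = sample_annulus_points(c(0, 0, 0), c(0, 0, 1),
                                       0.6 * R_cup, 0.95 * R_cup,
                                       spec$n_plane, sigma = sig,
                                       label = "plane1", scan_id = scan_id),
        plane2 = sample_annulus_points(c(0, 0, spec$plane_separation), n2,
                                       0.6 * R_cup, 0.95 * R_cup,
                                       spec$n_plane, sigma = sig,
                                       label = "plane2", scan_id = scan_id))
      if (spec$include_inner) {
        inner <- sample_sphere_points(c(0, 0, 0), r_inner, spec$n_inner,
                                      cap_direction = c(0, 0, -1),
                                      cap_angle = 90, sigma = sig,
                                      label = "cup_inner", scan_id = scan_id)
        if (scan_id == "post") {
          # wear displaces the worn (canonical +x) hemisphere of the liner
          worn <- inner$points[, 1] >= 0
          inner$points[worn, ] <- sweep(inner$points[worn, , drop = FALSE],
                                        2L, -spec$wear_vector_true)
        }
        clouds$cup_inner <- inner
      }

      outward <- list(
        cup_outer = function(p) p / sqrt(rowSums(p^2)),
        head = function(p) sweep(p, 2L, head_center) /
          sqrt(rowSums(sweep(p, 2L, head_center)^2)),
        plane1 = function(p) matrix(c(0, 0, 1), nrow(p), 3L, byrow = TRUE),
        plane2 = function(p) matrix(n2, nrow(p), 3L, byrow = TRUE))
      outlier_idx <- list()
      for (nm in intersect(names(clouds), names(outward))) {
        oi <- inject_outliers(clouds[[nm]], spec$outlier_fraction,
                              spec$outlier_min_offset, outward[[nm]])
        clouds[[nm]] <- oi$cloud
        outlier_idx[[nm]] <- oi$idx
      }

      motion <- rigid_transform(R_incl, c(0, 0, 0))
      if (spec$reposition) {
        motion <- compose_transforms(
          random_rigid_motion(spec$max_translation, spec$max_rotation), motion)
      }
      clouds <- lapply(clouds, function(cl) apply_transform(motion, cl))
      if (!is.null(spec$voxel_grid)) {
        clouds <- lapply(clouds, function(cl) {
          cl$points[, 3] <- round(cl$points[, 3] / spec$voxel_grid) * spec$voxel_grid
          cl
        })
      }
      list(scan = scan_data(cup_outer = clouds$cup_outer, head = clouds$head,
                            plane1 = clouds$plane1, plane2 = clouds$plane2,
                            cup_inner = clouds$cup_inner, scan_id = scan_id),
           outlier_idx = outlier_idx)
    }

    pre <- make_scan("pre", head_center_pre)
    post <- make_scan("post", head_center_post)
    truth <- wear_result(spec$wear_vector_true, method = "CT",
                         diagnostics = list(
                           outlier_idx = list(pre = pre$outlier_idx,
                                              post = post$outlier_idx),
                           spec = spec))
    list(pre = pre$scan, post = post$scan, truth = truth)
  })
}
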