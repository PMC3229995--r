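# --- wear measurement pipeline --------------------------------------------

#' Bundle the labelled clouds of one scan
#'
#' @param cup_outer,head,plane1,plane2 [point_cloud]s with matching labels
#' @param cup_inner optional [point_cloud] of the inner articulating surface
#' @param scan_id scan identifier; all clouds must share it
#' @return object of class `scan_data`
#' @export
scan_data <- function(cup_outer, head, plane1, plane2, cup_inner = NULL,
                      scan_id = cup_outer$scan_id) {
  clouds <- list(cup_outer = cup_outer, head = head,
                 plane1 = plane1, plane2 = plane2)
  if (!is.null(cup_inner)) clouds$cup_inner <- cup_inner
  for (nm in names(clouds)) {
    cl <- clouds[[nm]]
    if (!inherits(cl, "point_cloud")) abort_parse(nm, " is not a point_cloud")
    if (cl$label != nm) {
      abort_parse("cloud in slot '", nm, "' carries label '", cl$label, "'")
    }
    if (cl$scan_id != scan_id) {
      abort_parse("cloud '", nm, "' has scan_id '", cl$scan_id,
                  "', expected '", scan_id, "'")
    }
  }
  structure(c(clouds, list(scan_id = scan_id)), class = "scan_data")
}

#' @export
print.scan_data <- function(x, ...) {
  nm <- setdiff(names(x), "scan_id")
  cat(sprintf("<scan_data> %s: %s\n", x$scan_id,
              paste(sprintf("%s (%d)", nm,
                            vapply(x[nm], n_points, integer(1))), collapse = ", ")))
  invisible(x)
}

wear_result <- function(wear_vector, method, diagnostics = list()) {
  ang <- wear_angles(wear_vector)
  structure(list(linear_wear = vnorm(wear_vector),
                 wear_vector = as.numeric(wear_vector),
                 theta = ang$theta, phi = ang$phi,
                 angles_defined = ang$defined,
                 method = method, diagnostics = diagnostics),
            class = "wear_result")
}

#' @export
print.wear_result <- function(x, ...) {
  cat(sprintf("<wear_result> method %s\n", x$method))
  cat(sprintf("  linear wear: %.4f mm (display %.2f mm)\n",
              x$linear_wear, round(x$linear_wear, 2)))
  cat(sprintf("  wear vector (cup frame): (%.4f, %.4f, %.4f) mm\n",
              x$wear_vector[1], x$wear_vector[2], x$wear_vector[3]))
  if (x$angles_defined) {
    cat(sprintf("  theta %.1f deg, phi %.1f deg\n", x$theta, x$phi))
  } else {
    cat("  wear angles undefined (zero wear vector); reported as 0\n")
  }
  invisible(x)
}

#' Spherical angles of a wear vector
#'
#' Standard spherical convention in the cup frame: `theta` is the polar
#' angle from the frame z axis in `[0, 180]` degrees; `phi` is the azimuth
#' from the x axis, counter-clockwise about z, in `(-180, 180]` degrees.
#' A zero-length vector has no direction: both angles are reported as the
#' conventional 0 with `defined = FALSE` rather than NaN.
#'
#' @param wear_vector 3-vector, mm
#' @param tol vector norms below `tol` count as zero (default 1e-12 mm)
#' @return list with `theta`, `phi` (degrees) and logical `defined`
#' @examples
#' wear_angles(c(1, 0, 0)) # theta 90, phi 0
#' @export
wear_angles <- function(wear_vector, tol = 1e-12) {
  v <- as.numeric(wear_vector)
  stopifnot(length(v) == 3L)
  n <- vnorm(v)
  if (!is.finite(n) || n < tol) {
    return(list(theta = 0, phi = 0, defined = FALSE))
  }
  theta <- acos(max(-1, min(1, v[3] / n))) * 180 / pi
  phi <- atan2(v[2], v[1]) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  list(theta = theta, phi = phi, defined = TRUE)
}

# fit one surface with error context naming the surface and scan
fit_surface <- function(fitter, cloud, surface, scan_id, ...) {
  tryCatch(fitter(cloud, ...), cupwear_degeneracy = function(e) {
    abort_degenerate("fitting ", surface, " of scan '", scan_id, "': ",
                     conditionMessage(e))
  })
}

ct_fit_scan <- function(scan, filter_threshold, max_iterations) {
  id <- scan$scan_id
  cup <- fit_surface(fit_sphere, scan$cup_outer, "cup_outer", id,
                     filter_threshold = filter_threshold,
                     max_iterations = max_iterations)
  head <- fit_surface(fit_sphere, scan$head, "head", id,
                      filter_threshold = filter_threshold,
                      max_iterations = max_iterations)
  p1 <- fit_surface(fit_plane, scan$plane1, "plane1", id,
                    filter_threshold = filter_threshold,
                    max_iterations = max_iterations)
  p2 <- fit_surface(fit_plane, scan$plane2, "plane2", id,
                    filter_threshold = filter_threshold,
                    max_iterations = max_iterations)
  frame <- build_cup_frame(cup, p1, p2)
  list(cup = cup, head = head, plane1 = p1, plane2 = p2, frame = frame,
       head_in_frame = world_to_frame(frame, head$center))
}

fit_summary <- function(f) {
  out <- list(rms_residual = f$rms_residual, n_used = f$n_used,
              n_rejected = f$n_rejected)
  if (inherits(f, "sphere_fit")) {
    out$center <- f$center
    out$radius <- f$radius
    out$diameter <- 2 * f$radius
  } else {
    out$normal <- f$normal
    out$offset <- f$offset
  }
  out
}

scan_diagnostics <- function(fits) {
  lapply(fits[c("cup", "head", "plane1", "plane2")], fit_summary)
}

#' Linear wear from a pre-/post-wear scan pair (CT-style)
#'
#' Runs the full measurement on two labelled scans: fits the cup sphere, the
#' head sphere and both opening-face planes per scan, anchors each scan's
#' cup frame, and expresses each head center in its own cup frame. The wear
#' vector is the head-center displacement between scans in cup-frame
#' coordinates; linear wear is its norm, and theta/phi its spherical angles.
#' Because each scan is referred to its own cup geometry, the result is
#' invariant to independent rigid motions of either scan — repositioning the
#' object between acquisitions does not change the measurement.
#'
#' @param pre,post [scan_data] for the unworn and worn states
#' @param filter_threshold outlier elimination threshold in mm (default 0.5)
#' @param max_iterations elimination passes per fit (default 10)
#' @return a `wear_result` with `method = "CT"`; `diagnostics` carries the
#'   per-surface fit summaries for both scans
#' @export
ct_wear <- function(pre, post, filter_threshold = 0.5, max_iterations = 10L) {
  stopifnot(inherits(pre, "scan_data"), inherits(post, "scan_data"))
  fpre <- ct_fit_scan(pre, filter_threshold, max_iterations)
  fpost <- ct_fit_scan(post, filter_threshold, max_iterations)
  wv <- fpost$head_in_frame - fpre$head_in_frame
  wear_result(wv, method = "CT",
              diagnostics = list(pre = scan_diagnostics(fpre),
                                 post = scan_diagnostics(fpost)))
}

#' Partition an inner-surface cloud into worn and unworn hemispheres
#'
#' Splits by the sign of the cup-frame x coordinate: `x * worn_sign >= 0`
#' goes to the worn side. The hip simulator wears one side of the cup, so
#' the side convention is configurable for left/right cups via `worn_sign`.
#'
#' @param inner a [point_cloud] of the inner surface
#' @param frame the [cup_frame] to split in
#' @param worn_sign `+1` (default) if the worn hemisphere is at positive
#'   frame x, `-1` to flip
#' @return list of [point_cloud]s `worn_side` and `unworn_side` (order
#'   preserved), plus the index vectors `worn_idx`, `unworn_idx`
#' @export
split_hemispheres <- function(inner, frame, worn_sign = 1) {
  stopifnot(worn_sign %in% c(-1, 1))
  xloc <- world_to_frame(frame, inner$points)[, 1] * worn_sign
  worn <- xloc >= 0
  list(worn_side = cloud_subset(inner, which(worn)),
       unworn_side = cloud_subset(inner, which(!worn)),
       worn_idx = which(worn), unworn_idx = which(!worn))
}

cmm_fit_scan <- function(inner, planes, filter_threshold, max_iterations,
                         worn_sign) {
  id <- inner$scan_id
  p1 <- fit_surface(fit_plane, planes$plane1, "plane1", id,
                    filter_threshold = filter_threshold,
                    max_iterations = max_iterations)
  p2 <- fit_surface(fit_plane, planes$plane2, "plane2", id,
                    filter_threshold = filter_threshold,
                    max_iterations = max_iterations)
  # provisional frame from a sphere on the whole inner surface, used only to
  # separate the hemispheres
  s0 <- fit_surface(fit_sphere, inner, "cup_inner", id,
                    filter_threshold = filter_threshold,
                    max_iterations = max_iterations)
  frame0 <- build_cup_frame(s0, p1, p2)
  halves <- split_hemispheres(inner, frame0, worn_sign = worn_sign)
  if (n_points(halves$unworn_side) < 4L || n_points(halves$worn_side) < 4L) {
    abort_degenerate("scan '", id, "': a hemisphere has fewer than 4 inner ",
                     "points after the split")
  }
  s_unworn <- fit_surface(fit_sphere, halves$unworn_side, "cup_inner (unworn side)",
                          id, filter_threshold = filter_threshold,
                          max_iterations = max_iterations)
  frame <- build_cup_frame(s_unworn, p1, p2, dome_point = s0$centroid)
  s_worn <- fit_surface(fit_sphere, halves$worn_side, "cup_inner (worn side)",
                        id, filter_threshold = filter_threshold,
                        max_iterations = max_iterations)
  list(plane1 = p1, plane2 = p2, sphere_unworn = s_unworn,
       sphere_worn = s_worn, frame = frame,
       worn_center_in_frame = world_to_frame(frame, s_worn$center))
}

#' Linear wear from inner-surface digitizations (CMM-style)
#'
#' The tactile-probe reference variant: wear is defined as the displacement
#' of the midpoint of a sphere fitted to the worn hemisphere of the cup's
#' inner surface. Per scan, the frame is built from the (plastic) opening
#' face planes and a sphere fitted to the unworn hemisphere; the worn-
#' hemisphere sphere center is then expressed in that frame and the wear
#' vector is its displacement between scans.
#'
#' @param pre_inner,post_inner [point_cloud]s of the inner surface (label
#'   `cup_inner`)
#' @param pre_planes,post_planes lists with `plane1` and `plane2`
#'   [point_cloud]s for each scan
#' @param filter_threshold elimination threshold in mm (default 0.5)
#' @param max_iterations elimination passes per fit (default 10)
#' @param worn_sign `+1` if the worn hemisphere is at positive frame x
#' @return a `wear_result` with `method = "CMM"`
#' @export
cmm_wear <- function(pre_inner, post_inner, pre_planes, post_planes,
                     filter_threshold = 0.5, max_iterations = 10L,
                     worn_sign = 1) {
  fpre <- cmm_fit_scan(pre_inner, pre_planes, filter_threshold,
                       max_iterations, worn_sign)
  fpost <- cmm_fit_scan(post_inner, post_planes, filter_threshold,
                        max_iterations, worn_sign)
  wv <- fpost$worn_center_in_frame - fpre$worn_center_in_frame
  diag_of <- function(f) list(plane1 = fit_summary(f$plane1),
                              plane2 = fit_summary(f$plane2),
                              sphere_unworn = fit_summary(f$sphere_unworn),
                              sphere_worn = fit_summary(f$sphere_worn))
  wear_result(wv, method = "CMM",
              diagnostics = list(pre = diag_of(fpre), post = diag_of(fpost)))
}

#' Convert gravimetric mass loss to wear volume
#'
#' Divides the mass loss by the polyethylene density. The default density
#' 0.935 mg/mm^3 (935 kg/m^3) is that of the GUR1020 UHMWPE cups. Negative
#' mass loss (fluid soak gain) yields a negative volume.
#'
#' @param mass_loss_mg mass loss in mg
#' @param density_mg_mm3 density in mg per mm^3 (> 0), default 0.935
#' @return wear volume in mm^3
#' @examples
#' wear_volume_from_mass(200) # 213.90 mm^3
#' @export
wear_volume_from_mass <- function(mass_loss_mg, density_mg_mm3 = 0.935) {
  if (!is.numeric(density_mg_mm3) || density_mg_mm3 <= 0) {
    abort_parse("density must be positive (mg/mm^3)")
  }
  mass_loss_mg / density_mg_mm3
}
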