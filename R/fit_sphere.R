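# --- sphere fitting -------------------------------------------------------
#
# Two-stage fit: a closed-form algebraic (linearized) solution initializes a
# geometric orthogonal-distance least-squares refinement (Levenberg-
# Marquardt). The algebraic stage minimizes sum((|p|^2 - 2 p.c - k)^2) which
# is linear in (c, k) with k = r^2 - |c|^2; the geometric stage minimizes
# sum((|p - c| - r)^2), the orthogonal residual the fit reports.

# closed-form algebraic fit; also used as an independent oracle in tests
sphere_fit_algebraic <- function(pts) {
  if (nrow(pts) < 4L) abort_degenerate("sphere fit needs at least 4 points")
  A <- cbind(2 * pts, 1)
  y <- rowSums(pts^2)
  qa <- qr(A)
  if (qa$rank < 4L) {
    abort_degenerate("sphere fit is degenerate: points are coplanar or collinear")
  }
  beta <- qr.coef(qa, y)
  center <- unname(beta[1:3])
  r2 <- unname(beta[4]) + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    abort_degenerate("sphere fit is degenerate: non-positive squared radius")
  }
  list(center = center, radius = sqrt(r2))
}

sphere_residuals <- function(par, pts) {
  d <- sqrt((pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2 + (pts[, 3] - par[3])^2)
  d - par[4]
}

sphere_jacobian <- function(par, pts) {
  dx <- pts[, 1] - par[1]
  dy <- pts[, 2] - par[2]
  dz <- pts[, 3] - par[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  d[d < 1e-12] <- 1e-12
  cbind(-dx / d, -dy / d, -dz / d, -1)
}

# geometric orthogonal-distance fit on a raw coordinate matrix
sphere_fit_geometric <- function(pts) {
  init <- sphere_fit_algebraic(pts)
  par0 <- c(init$center, init$radius)
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, gtol = 0,
                                    maxiter = 200)
  fit <- minpack.lm::nls.lm(par = par0, fn = sphere_residuals,
                            jac = sphere_jacobian, pts = pts, control = ctl)
  par <- unname(fit$par)
  if (par[4] <= 0) abort_degenerate("sphere fit collapsed to non-positive radius")
  list(center = par[1:3], radius = par[4])
}

#' Fit a sphere with residual-based outlier elimination
#'
#' Fits center and radius minimizing the sum of squared orthogonal residuals
#' `(|p - c| - r)^2`, then eliminates every point lying more than
#' `filter_threshold` from the fitted spherical surface and refits, repeating
#' until no further point is removed (or `max_iterations` elimination passes
#' have run). With `max_iterations = 1` a single eliminate-then-refit pass is
#' performed. The comparison is strict: a residual exactly equal to the
#' threshold is retained.
#'
#' @param cloud a [point_cloud] (any label)
#' @param filter_threshold elimination threshold in mm (> 0), default 0.5 mm
#' @param max_iterations maximum number of elimination passes (default 10)
#' @return an object of class `sphere_fit`: `center` (mm), `radius` (mm),
#'   `rms_residual` (mm over retained points), `n_used`, `n_rejected`
#'   (`n_used + n_rejected` equals the input size), `rejected_idx` (row
#'   indices into the input cloud), `centroid` of the retained points, and
#'   `n_elimination_passes`.
#' @examples
#' octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
#'               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
#' fit_sphere(point_cloud(octa, "head"))
#' @export
fit_sphere <- function(cloud, filter_threshold = 0.5, max_iterations = 10L) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud, "head")
  if (!is.numeric(filter_threshold) || filter_threshold <= 0) {
    abort_parse("filter_threshold must be positive (mm)")
  }
  max_iterations <- as.integer(max_iterations)
  stopifnot(max_iterations >= 1L)

  pts_all <- cloud$points
  n_in <- nrow(pts_all)
  keep <- seq_len(n_in)
  rejected <- integer(0)
  removed_last <- TRUE
  passes <- 0L
  fit <- NULL
  while (removed_last && passes < max_iterations) {
    passes <- passes + 1L
    if (length(keep) < 4L) {
      abort_degenerate("sphere fit: fewer than 4 points remain after elimination")
    }
    fit <- sphere_fit_geometric(pts_all[keep, , drop = FALSE])
    res <- abs(sphere_residuals(c(fit$center, fit$radius),
                                pts_all[keep, , drop = FALSE]))
    drop_i <- which(res > filter_threshold)
    removed_last <- length(drop_i) > 0L
    if (removed_last) {
      rejected <- c(rejected, keep[drop_i])
      keep <- keep[-drop_i]
    }
  }
  if (length(keep) < 4L) {
    abort_degenerate("sphere fit: fewer than 4 points remain after elimination")
  }
  if (removed_last) { # last pass removed points: refit on the survivors
    fit <- sphere_fit_geometric(pts_all[keep, , drop = FALSE])
    res <- abs(sphere_residuals(c(fit$center, fit$radius),
                                pts_all[keep, , drop = FALSE]))
    if (max_iterations > 1L && any(res > filter_threshold)) {
      abort_convergence("sphere outlier elimination did not reach a fixed ",
                        "point within ", max_iterations, " passes")
    }
  } else {
    res <- abs(sphere_residuals(c(fit$center, fit$radius),
                                pts_all[keep, , drop = FALSE]))
  }
  used <- pts_all[keep, , drop = FALSE]
  structure(list(center = fit$center,
                 radius = fit$radius,
                 rms_residual = sqrt(mean(res^2)),
                 n_used = length(keep),
                 n_rejected = length(rejected),
                 rejected_idx = sort(rejected),
                 centroid = colMeans(used),
                 n_elimination_passes = passes,
                 label = cloud$label,
                 scan_id = cloud$scan_id),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms %.4f mm, %d used / %d rejected\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual,
    x$n_used, x$n_rejected))
  invisible(x)
}
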