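# --- plane fitting --------------------------------------------------------
#
# Total least squares: the plane through the centroid whose normal is the
# right singular vector of the centered coordinates with smallest singular
# value minimizes the sum of squared orthogonal distances.

plane_fit_tls <- function(pts) {
  if (nrow(pts) < 3L) abort_degenerate("plane fit needs at least 3 points")
  m <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, m), nu = 0)
  # rank < 2 means the points are collinear (or a single point)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) {
    abort_degenerate("plane fit is degenerate: points are collinear")
  }
  normal <- sv$v[, 3]
  list(normal = normal, offset = sum(normal * m), centroid = m)
}

plane_residuals <- function(normal, offset, pts) {
  abs(drop(pts %*% normal) - offset)
}

# deterministic sign: make the largest-magnitude normal component positive
orient_plane <- function(fit, reference_point = NULL) {
  flip <- if (!is.null(reference_point)) {
    sum(fit$normal * reference_point) - fit$offset < 0
  } else {
    fit$normal[which.max(abs(fit$normal))] < 0
  }
  if (flip) {
    fit$normal <- -fit$normal
    fit$offset <- -fit$offset
  }
  fit
}

#' Fit a plane with residual-based outlier elimination
#'
#' Total-least-squares plane fit (minimizing orthogonal distances), with the
#' same eliminate-and-refit loop as [fit_sphere]: points more than
#' `filter_threshold` from the fitted plane are eliminated and the plane is
#' refitted until a fixed point is reached. The normal is a unit vector; when
#' `reference_point` is supplied the normal is oriented so that the reference
#' point lies on its positive side, otherwise the sign is fixed
#' deterministically (largest-magnitude component positive).
#'
#' @param cloud a [point_cloud] (typically label `plane1` or `plane2`)
#' @param filter_threshold elimination threshold in mm (> 0), default 0.5 mm
#' @param max_iterations maximum elimination passes (default 10)
#' @param reference_point optional 3-vector used to orient the normal
#' @return an object of class `plane_fit`: unit `normal`, `offset` (signed
#'   distance of the plane from the origin along the normal, mm),
#'   `rms_residual`, `n_used`, `n_rejected`, `rejected_idx`, `centroid` of
#'   retained points, `n_elimination_passes`.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
#' fit_plane(point_cloud(sq, "plane1"))
#' @export
fit_plane <- function(cloud, filter_threshold = 0.5, max_iterations = 10L,
                      reference_point = NULL) {
  if (!inherits(cloud, "point_cloud")) cloud <- point_cloud(cloud, "plane1")
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
    if (length(keep) < 3L) {
      abort_degenerate("plane fit: fewer than 3 points remain after elimination")
    }
    fit <- plane_fit_tls(pts_all[keep, , drop = FALSE])
    res <- plane_residuals(fit$normal, fit$offset, pts_all[keep, , drop = FALSE])
    drop_i <- which(res > filter_threshold)
    removed_last <- length(drop_i) > 0L
    if (removed_last) {
      rejected <- c(rejected, keep[drop_i])
      keep <- keep[-drop_i]
    }
  }
  if (length(keep) < 3L) {
    abort_degenerate("plane fit: fewer than 3 points remain after elimination")
  }
  if (removed_last) {
    fit <- plane_fit_tls(pts_all[keep, , drop = FALSE])
    res <- plane_residuals(fit$normal, fit$offset, pts_all[keep, , drop = FALSE])
    if (max_iterations > 1L && any(res > filter_threshold)) {
      abort_convergence("plane outlier elimination did not reach a fixed ",
                        "point within ", max_iterations, " passes")
    }
  } else {
    res <- plane_residuals(fit$normal, fit$offset, pts_all[keep, , drop = FALSE])
  }
  fit <- orient_plane(fit, reference_point)
  structure(list(normal = fit$normal,
                 offset = fit$offset,
                 rms_residual = sqrt(mean(res^2)),
                 n_used = length(keep),
                 n_rejected = length(rejected),
                 rejected_idx = sort(rejected),
                 centroid = fit$centroid,
                 n_elimination_passes = passes,
                 label = cloud$label,
                 scan_id = cloud$scan_id),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf(
    "<plane_fit> normal (%.4f, %.4f, %.4f), offset %.4f mm, rms %.4f mm, %d used / %d rejected\n",
    x$normal[1], x$normal[2], x$normal[3], x$offset, x$rms_residual,
    x$n_used, x$n_rejected))
  invisible(x)
}
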