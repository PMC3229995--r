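#' Surface labels recognized on point clouds
#'
#' The closed set of surface labels used throughout the package: the outer
#' (metal-backed) cup surface, the inner articulating cup surface, the
#' femoral head, and the two cup opening faces.
#'
#' @export
SURFACE_LABELS <- c("cup_outer", "cup_inner", "head", "plane1", "plane2")

#' Create a labelled 3D point cloud
#'
#' A `point_cloud` is the elementary data container: an ordered set of 3D
#' coordinates in millimetres digitized on one surface of one scan.
#'
#' @param points numeric matrix (or data frame) with 3 columns, one row per
#'   point, coordinates in mm. Row order is preserved by every operation.
#' @param label surface label, one of [SURFACE_LABELS].
#' @param scan_id identifier of the scan the cloud belongs to, e.g. `"pre"`
#'   or `"post"`.
#' @return an object of class `point_cloud` with elements `points`
#'   (n x 3 matrix with columns x, y, z), `label`, `scan_id`.
#' @examples
#' pc <- point_cloud(diag(3), label = "head", scan_id = "pre")
#' n_points(pc)
#' @export
point_cloud <- function(points, label, scan_id = "scan") {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L) {
    abort_parse("point cloud needs exactly 3 coordinate columns, got ", ncol(pts))
  }
  storage.mode(pts) <- "double"
  if (nrow(pts) < 1L) abort_parse("point cloud needs at least one point")
  if (!all(is.finite(pts))) abort_parse("non-finite coordinate in point cloud")
  if (length(label) != 1L || !label %in% SURFACE_LABELS) {
    abort_parse("unknown surface label '", paste(label, collapse = ","),
                "'; expected one of: ", paste(SURFACE_LABELS, collapse = ", "))
  }
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(list(points = pts, label = label, scan_id = as.character(scan_id)),
            class = "point_cloud")
}

#' Number of points in a point cloud
#' @param cloud a [point_cloud]
#' @return integer count
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %s / %s: %d points\n", x$scan_id, x$label, n_points(x)))
  invisible(x)
}

# subset a cloud by row indices, preserving order
cloud_subset <- function(cloud, idx) {
  out <- cloud
  out$points <- cloud$points[idx, , drop = FALSE]
  out
}

#' Split a point cloud by a residual threshold
#'
#' Partitions a cloud into the points retained on a surface and those
#' eliminated as artifacts, using the strict "more than" rule: a point is
#' rejected only if its residual distance exceeds the threshold, so a
#' residual exactly equal to the threshold is retained. Row order is
#' preserved in both outputs.
#'
#' @param cloud a [point_cloud]
#' @param residual_fn function mapping the n x 3 coordinate matrix to a
#'   vector of n nonnegative distances in mm
#' @param threshold rejection threshold in mm (> 0); the default 0.5 mm is
#'   the customary metal-artifact filter (about 1 SD of CT surface noise)
#' @return list with `retained` and `rejected` point clouds (either may be
#'   empty of rows only conceptually: `rejected` is `NULL`-points-free; both
#'   carry index vectors `retained_idx`, `rejected_idx` into the input)
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 0.6)), "plane1")
#' out <- filter_to_surface(pc, function(p) abs(p[, 3]), threshold = 0.5)
#' out$rejected_idx
#' @export
filter_to_surface <- function(cloud, residual_fn, threshold = 0.5) {
  stopifnot(is.function(residual_fn))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort_parse("threshold must be a single positive number (mm)")
  }
  res <- residual_fn(cloud$points)
  if (length(res) != n_points(cloud)) {
    abort_parse("residual_fn returned ", length(res), " values for ",
                n_points(cloud), " points")
  }
  keep <- res <= threshold
  list(retained = cloud_subset(cloud, which(keep)),
       rejected = cloud_subset(cloud, which(!keep)),
       retained_idx = which(keep),
       rejected_idx = which(!keep))
}
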