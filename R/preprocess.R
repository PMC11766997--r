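#' Rotation specification for the two-phase frame correction
#'
#' The raw side-view scans are acquired with the sensor frame rotated
#' relative to the orchard frame (rows along X, Z up). The correction is
#' a counterclockwise rotation by `theta` about Z followed by a rotation
#' by `phi` about Y. The Y rotation uses the clockwise sign convention
#' (the matrix carries -sin(phi) in row 1 and +sin(phi) in row 3);
#' set `y_clockwise = FALSE` for the standard counterclockwise form.
#'
#' @param theta angle about Z in degrees, counterclockwise positive.
#' @param phi angle about Y in degrees, clockwise positive by default.
#' @param y_clockwise logical; use the clockwise Y convention (default).
#' @return An object of class `rotation_spec`.
#' @examples
#' rotation_spec(90, 90)
#' @export
rotation_spec <- function(theta = 90, phi = 90, y_clockwise = TRUE) {
  stopifnot(is.finite(theta), is.finite(phi))
  structure(list(theta = theta, phi = phi, y_clockwise = isTRUE(y_clockwise)),
            class = "rotation_spec")
}

#' Rotation matrix about Z (counterclockwise)
#' @param theta_deg angle in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), nrow = 3, byrow = TRUE)
}

#' Rotation matrix about Y
#'
#' With `clockwise = TRUE` (the acquisition convention) the matrix is
#' `[[cos, 0, -sin], [0, 1, 0], [sin, 0, cos]]`, i.e. the transpose of
#' the standard counterclockwise form.
#'
#' @param phi_deg angle in degrees.
#' @param clockwise logical sign convention.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix_y <- function(phi_deg, clockwise = TRUE) {
  p <- phi_deg * pi / 180
  if (clockwise) {
    matrix(c(cos(p), 0, -sin(p),
             0,      1,  0,
             sin(p), 0,  cos(p)), nrow = 3, byrow = TRUE)
  } else {
    matrix(c(cos(p),  0, sin(p),
             0,       1, 0,
             -sin(p), 0, cos(p)), nrow = 3, byrow = TRUE)
  }
}

# combined correction matrix: Z rotation first, then Y rotation
rotation_matrix <- function(spec) {
  rotation_matrix_y(spec$phi, spec$y_clockwise) %*% rotation_matrix_z(spec$theta)
}

#' Apply the two-phase coordinate correction
#'
#' Each point is rotated counterclockwise about Z by `spec$theta`, then
#' about Y by `spec$phi` under the chosen Y sign convention. Lengths and
#' pairwise distances are preserved.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param spec a [rotation_spec()].
#' @return The rotated [point_cloud()].
#' @examples
#' pc <- point_cloud(rbind(c(1, 0, 0)))
#' transform_coordinates(pc, rotation_spec(theta = 90, phi = 0))$points
#' @export
transform_coordinates <- function(cloud, spec = rotation_spec()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "rotation_spec"))
  if (n_points(cloud) == 0L) stop("cannot transform an empty cloud")
  R <- rotation_matrix(spec)
  point_cloud(cloud$points %*% t(R), intensity = cloud$intensity,
              frame_id = cloud$frame_id)
}

#' Undo the frame correction (emulate the raw sensor pose)
#'
#' Applies the exact inverse of [transform_coordinates()], so a cloud
#' generated in the orchard frame can be put into the raw acquisition
#' pose and the correction exercised end to end:
#' `transform_coordinates(apply_sensor_pose(c, s), s)` restores `c`.
#'
#' @inheritParams transform_coordinates
#' @return The de-rotated [point_cloud()].
#' @export
apply_sensor_pose <- function(cloud, spec = rotation_spec()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(spec, "rotation_spec"))
  if (n_points(cloud) == 0L) stop("cannot transform an empty cloud")
  R <- rotation_matrix(spec)
  point_cloud(cloud$points %*% R, intensity = cloud$intensity,
              frame_id = cloud$frame_id)
}

#' Radius outlier removal
#'
#' A point is retained iff at least `min_neighbors` *other* points lie
#' within Euclidean distance `radius` of it. Decisions are simultaneous:
#' neighbor counts are computed once on the input cloud, so the result
#' does not depend on any removal order. The defaults follow the
#' field-calibrated values (32 neighbors within 0.01); the radius is
#' interpreted in meters and both parameters should be rescaled to the
#' point density at hand (see the package vignette).
#'
#' @param cloud a [point_cloud()] (may be empty).
#' @param min_neighbors required neighbor count, >= 1.
#' @param radius neighborhood radius in meters, > 0.
#' @return List with `cloud` (retained points), `removed` (logical mask
#'   over the input, `TRUE` = removed) and `neighbor_counts`.
#' @export
radius_outlier_removal <- function(cloud, min_neighbors = 32, radius = 0.01) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (radius <= 0) stop("`radius` must be positive")
  if (min_neighbors < 1) stop("`min_neighbors` must be at least 1")
  n <- n_points(cloud)
  if (n == 0L)
    return(list(cloud = cloud, removed = logical(0), neighbor_counts = integer(0)))
  counts <- .kd_neighbor_counts(cloud$points, radius)
  removed <- counts < min_neighbors
  list(cloud = subset_cloud(cloud, !removed), removed = removed,
       neighbor_counts = counts)
}

#' Voxel-grid downsampling
#'
#' Space is partitioned into axis-aligned cubes of edge `voxel` anchored
#' at the coordinate origin; each occupied voxel contributes exactly one
#' output point, the centroid of its members. Intensities, when present,
#' are averaged the same way.
#'
#' @param cloud a [point_cloud()].
#' @param voxel cube edge length in meters, > 0.
#' @return The downsampled [point_cloud()]; one point per occupied voxel.
#' @export
voxel_downsample <- function(cloud, voxel = 0.01) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (voxel <= 0) stop("`voxel` must be positive")
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  key_ix <- floor(cloud$points / voxel)
  key <- paste(key_ix[, 1], key_ix[, 2], key_ix[, 3], sep = "/")
  vals <- cbind(cloud$points, count = 1,
                if (!is.null(cloud$intensity)) intensity = cloud$intensity)
  sums <- rowsum(vals, group = key, reorder = TRUE)
  cnt <- sums[, "count"]
  pts <- sums[, 1:3, drop = FALSE] / cnt
  inten <- if (!is.null(cloud$intensity)) sums[, "intensity"] / cnt
  point_cloud(pts, intensity = inten, frame_id = cloud$frame_id)
}

#' Statistical outlier removal
#'
#' The optional second denoising filter: for every point the mean
#' distance to its `k` nearest neighbors is computed, and points whose
#' mean distance exceeds the cloud-wide mean by more than `alpha`
#' standard deviations are removed. Unlike [radius_outlier_removal()]
#' this separates points lifted off a sampled surface even when they
#' still see many neighbors, so it is useful on single-population
#' clouds (e.g. the canopy after ground removal); on mixed-density
#' scenes the global threshold is less selective.
#'
#' @param cloud a [point_cloud()].
#' @param k number of nearest neighbors, >= 1.
#' @param alpha standard-deviation multiplier of the cutoff.
#' @return List with `cloud` (retained points), `removed` mask and the
#'   per-point `mean_knn_dist`.
#' @export
statistical_outlier_removal <- function(cloud, k = 10, alpha = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (k < 1) stop("`k` must be at least 1")
  n <- n_points(cloud)
  if (n <= 2L)
    return(list(cloud = cloud, removed = logical(n),
                mean_knn_dist = rep(0, n)))
  md <- .kd_knn_mean_dist(cloud$points, as.integer(min(k, n - 1L)))
  cutoff <- mean(md) + alpha * stats::sd(md)
  removed <- md > cutoff
  list(cloud = subset_cloud(cloud, !removed), removed = removed,
       mean_knn_dist = md)
}

#' Build a kd-tree spatial index over a cloud
#'
#' The tree recursively partitions the points with split axes cycling
#' X, then Y, then Z, and supports exact axis-aligned range queries and
#' radius queries.
#'
#' @param cloud a [point_cloud()] or an n x 3 coordinate matrix.
#' @return An object of class `kd_tree` wrapping the index.
#' @export
kd_tree <- function(cloud) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  stopifnot(ncol(pts) == 3L)
  storage.mode(pts) <- "double"
  structure(list(ptr = .kd_build(pts), n = nrow(pts)), class = "kd_tree")
}

#' @export
print.kd_tree <- function(x, ...) {
  cat(sprintf("kd_tree over %d points (split axes X -> Y -> Z)\n", x$n))
  invisible(x)
}

#' Exact axis-aligned range query on a kd-tree
#'
#' @param tree a [kd_tree()].
#' @param box an [roi_box()] (closed on all faces).
#' @return Sorted integer indices of the points inside the box.
#' @export
kd_range_query <- function(tree, box) {
  stopifnot(inherits(tree, "kd_tree"))
  if (!inherits(box, "roi_box")) stop("`box` must be an roi_box")
  if (tree$n == 0L) return(integer(0))
  .kd_box_query(tree$ptr, box$min, box$max)
}

#' Radius query on a kd-tree
#' @param tree a [kd_tree()].
#' @param center numeric length-3 query point.
#' @param radius search radius in meters.
#' @return Sorted integer indices of points within `radius` of `center`.
#' @export
kd_radius_query <- function(tree, center, radius) {
  stopifnot(inherits(tree, "kd_tree"), radius > 0)
  if (tree$n == 0L) return(integer(0))
  .kd_radius_query(tree$ptr, as.numeric(center), radius)
}
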