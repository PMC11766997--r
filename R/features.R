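#' Tree height from a single-tree cloud
#'
#' Height is the vertical extent of the cloud: `Htree = Hmax - Hmin`
#' with `Hmax`/`Hmin` the largest and smallest z coordinates. For
#' plane-referenced height pass the fitted ground plane; `Hmin` is then
#' the plane elevation under the cloud's horizontal centroid.
#'
#' @param cloud a non-empty [point_cloud()] holding one tree.
#' @param plane optional `plane_model`; when given, the height is
#'   measured from the plane instead of the lowest point.
#' @return List with `h_max`, `h_min` and `h_tree` (meters).
#' @examples
#' pc <- point_cloud(cbind(0, 0, c(0.45, 1.2, 3.5)))
#' tree_height(pc)$h_tree
#' @export
tree_height <- function(cloud, plane = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cannot measure an empty cloud")
  h_max <- max(cloud$points[, 3])
  if (is.null(plane)) {
    h_min <- min(cloud$points[, 3])
  } else {
    stopifnot(inherits(plane, "plane_model"))
    ctr <- colMeans(cloud$points)
    nrm <- plane$normal
    if (abs(nrm[3]) < 1e-12) stop("plane is vertical; cannot reference height to it")
    h_min <- -(plane$offset + nrm[1] * ctr[1] + nrm[2] * ctr[2]) / nrm[3]
  }
  list(h_max = h_max, h_min = h_min, h_tree = h_max - h_min)
}

#' Axis-aligned bounding box of a cloud
#'
#' @param cloud a non-empty [point_cloud()].
#' @return An object of class `bounding_box`: `min`, `max`, `extent`
#'   (per axis, meters) and `volume` (m^3). A zero-thickness box (all
#'   points coplanar along an axis) triggers a warning.
#' @export
bounding_box <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L) stop("cannot bound an empty cloud")
  mn <- apply(cloud$points, 2, min)
  mx <- apply(cloud$points, 2, max)
  extent <- mx - mn
  if (any(extent == 0))
    warning("flat bounding box: zero extent on some axis")
  structure(list(min = mn, max = mx, extent = extent,
                 volume = prod(extent)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding_box: %.3f x %.3f x %.3f m, volume %.3f m^3\n",
              x$extent[1], x$extent[2], x$extent[3], x$volume))
  invisible(x)
}

#' Canopy volume from the bounding box
#'
#' The sensor-side canopy volume is the volume of the axis-aligned
#' bounding box of the canopy cloud. Side-view scans only see one face
#' of the crown, so the cross-row (y) extent may be under-represented;
#' when a manually measured crown width is supplied it replaces the
#' y extent and the substitution is flagged.
#'
#' @param cloud a non-empty canopy [point_cloud()] (trunk and ground
#'   excluded upstream, e.g. by a z-floor crop).
#' @param measured_width optional cross-row crown width (m), > 0.
#' @return List with `volume` (m^3), `width_adjusted` flag, the `bbox`
#'   used and the effective `extent`.
#' @export
canopy_volume_bbox <- function(cloud, measured_width = NULL) {
  bb <- bounding_box(cloud)
  extent <- bb$extent
  adjusted <- FALSE
  if (!is.null(measured_width)) {
    if (measured_width <= 0) stop("`measured_width` must be positive")
    extent[2] <- measured_width
    adjusted <- TRUE
  }
  list(volume = prod(extent), width_adjusted = adjusted, bbox = bb,
       extent = extent)
}

#' Manual (ellipsoid) canopy volume from field measurements
#'
#' The ground-truth comparator treats the crown as an ellipsoid with
#' horizontal diameters `D1`, `D2` and vertical extent equal to the
#' mean canopy depth seen from the two measuring positions:
#' `CVm = (pi/6) * D1 * D2 * ((Ht1 - Hs1) + (Ht2 - Hs2)) / 2`.
#'
#' @param d1,d2 crown diameters (m), measured from two perpendicular
#'   positions.
#' @param ht1,hs1 canopy top and base reference heights from position 1 (m).
#' @param ht2,hs2 the same from position 2 (m).
#' @return Canopy volume in m^3.
#' @examples
#' manual_canopy_volume(2, 2, 2, 0, 2, 0) # sphere of diameter 2: 4*pi/3
#' @export
manual_canopy_volume <- function(d1, d2, ht1, hs1, ht2, hs2) {
  if (d1 < 0 || d2 < 0) stop("crown diameters must be non-negative")
  if (hs1 < 0 || hs2 < 0 || ht1 < hs1 || ht2 < hs2)
    stop("reference heights must satisfy Ht >= Hs >= 0")
  (pi / 6) * d1 * d2 * 0.5 * ((ht1 - hs1) + (ht2 - hs2))
}

#' Centroid of a point set
#'
#' @param points a [point_cloud()] or an n x 3 coordinate matrix, n >= 1.
#' @return Numeric length-3 centroid (arithmetic mean per coordinate).
#' @export
cloud_centroid <- function(points) {
  pts <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  if (nrow(pts) == 0L) stop("cannot take the centroid of an empty set")
  colMeans(pts)
}

#' Tree and row spacing from cluster centroids
#'
#' Tree spacing is the planar (x-y) Euclidean distance between
#' consecutive tree centroids within a row. Row spacing is reported per
#' consecutive row pair, either between row centroids (the mean of the
#' row's tree centroids; default) or as the mean distance between
#' opposite trees paired by position in row.
#'
#' @param trees data frame with columns `tree_id`, `row_id`,
#'   `position_in_row`, `x`, `y` (e.g. `cluster_trees(...)$trees`).
#' @param row_method `"row-centroid"` (default) or `"tree-to-tree"`.
#' @return An object of class `spacing_result`: data frames
#'   `tree_spacing` (`row_id`, `from`, `to`, `distance`) and
#'   `row_spacing` (`from_row`, `to_row`, `distance`), meters.
#' @export
spacing <- function(trees, row_method = c("row-centroid", "tree-to-tree")) {
  row_method <- match.arg(row_method)
  trees <- as.data.frame(trees)
  need <- c("tree_id", "row_id", "position_in_row", "x", "y")
  if (!all(need %in% names(trees)))
    stop("`trees` must have columns ", paste(need, collapse = ", "))
  rows <- sort(unique(trees$row_id))
  if (nrow(trees) < 2L) stop("spacing needs at least 2 trees")

  planar <- function(a, b) sqrt(sum((a - b)^2))

  ts <- list()
  for (r in rows) {
    tr <- trees[trees$row_id == r, ]
    tr <- tr[order(tr$position_in_row), ]
    if (nrow(tr) < 2L) next
    for (i in seq_len(nrow(tr) - 1L)) {
      ts[[length(ts) + 1L]] <- data.frame(
        row_id = r, from = tr$tree_id[i], to = tr$tree_id[i + 1L],
        distance = planar(c(tr$x[i], tr$y[i]), c(tr$x[i + 1L], tr$y[i + 1L])))
    }
  }
  tree_spacing <- if (length(ts)) do.call(rbind, ts) else
    data.frame(row_id = integer(0), from = integer(0), to = integer(0),
               distance = numeric(0))

  rs <- list()
  if (length(rows) >= 2L) {
    for (i in seq_len(length(rows) - 1L)) {
      r1 <- trees[trees$row_id == rows[i], ]
      r2 <- trees[trees$row_id == rows[i + 1L], ]
      d <- if (row_method == "row-centroid") {
        planar(c(mean(r1$x), mean(r1$y)), c(mean(r2$x), mean(r2$y)))
      } else {
        common <- intersect(r1$position_in_row, r2$position_in_row)
        if (length(common) == 0L)
          stop("tree-to-tree row spacing needs matching positions in both rows")
        mean(vapply(common, function(p) {
          a <- r1[r1$position_in_row == p, ]
          b <- r2[r2$position_in_row == p, ]
          planar(c(a$x, a$y), c(b$x, b$y))
        }, numeric(1)))
      }
      rs[[length(rs) + 1L]] <- data.frame(from_row = rows[i],
                                          to_row = rows[i + 1L], distance = d)
    }
  }
  row_spacing <- if (length(rs)) do.call(rbind, rs) else
    data.frame(from_row = integer(0), to_row = integer(0),
               distance = numeric(0))

  structure(list(tree_spacing = tree_spacing, row_spacing = row_spacing,
                 row_method = row_method),
            class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("spacing_result (%s): %d tree gap(s), %d row gap(s)\n",
              x$row_method, nrow(x$tree_spacing), nrow(x$row_spacing)))
  if (nrow(x$tree_spacing))
    cat(sprintf("  tree spacing: mean %.3f m\n", mean(x$tree_spacing$distance)))
  if (nrow(x$row_spacing))
    cat(sprintf("  row spacing:  mean %.3f m\n", mean(x$row_spacing$distance)))
  invisible(x)
}
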