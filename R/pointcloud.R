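#' Construct a point cloud
#'
#' A `point_cloud` is the unit every pipeline stage consumes and produces:
#' an n x 3 matrix of Cartesian coordinates in meters (columns `x`, `y`,
#' `z`), an optional per-point intensity vector, and an optional
#' acquisition-frame tag.
#'
#' @param points numeric matrix (or data frame) with 3 columns, meters.
#' @param intensity optional numeric vector of length `nrow(points)`.
#' @param frame_id optional scalar tag identifying the acquisition frame.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points, intensity = NULL, frame_id = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0L) {
    points <- matrix(numeric(0), ncol = 3)
  }
  if (ncol(points) != 3L)
    stop("`points` must have exactly 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("all coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  rownames(points) <- NULL
  if (!is.null(intensity)) {
    intensity <- as.numeric(intensity)
    if (length(intensity) != nrow(points))
      stop("`intensity` must have one value per point")
  }
  structure(list(points = points, intensity = intensity, frame_id = frame_id),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- n_points(x)
  cat(sprintf("point_cloud: %d points%s%s\n", n,
              if (!is.null(x$intensity)) " (+intensity)" else "",
              if (!is.null(x$frame_id)) sprintf(" [frame %s]", x$frame_id) else ""))
  if (n > 0) {
    r <- apply(x$points, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

# internal: subset a cloud by row index, carrying intensity along
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              intensity = if (!is.null(cloud$intensity)) cloud$intensity[idx],
              frame_id = cloud$frame_id)
}

#' Axis-aligned region of interest
#'
#' @param min,max numeric length-3 lower/upper corners (x, y, z), meters.
#' @return An object of class `roi_box`.
#' @examples
#' roi_box(c(0, 0, 0), c(1, 1, 1))
#' @export
roi_box <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  if (length(min) != 3L || length(max) != 3L)
    stop("`min` and `max` must each have 3 elements")
  if (any(!is.finite(min)) || any(!is.finite(max)))
    stop("box corners must be finite")
  if (any(min > max))
    stop("degenerate box: `min` exceeds `max` on some axis")
  structure(list(min = min, max = max), class = "roi_box")
}
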