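#' Specification for a synthetic orchard scene
#'
#' Describes a regular planting of spindle-form trees in parallel rows
#' (rows run along X, Z is up) together with the sampling and noise
#' model used to emulate a terrestrial LiDAR scan of it. The defaults
#' describe a dense spindle apple planting: two rows of fifteen trees at 3.2 m tree
#' spacing and 3.4 m row spacing, tree heights between 2.5 and 3.55 m,
#' and 1 cm isotropic range noise (within the sensor's typical +/- 3 cm
#' accuracy).
#'
#' Per-tree heights and crown diameters are drawn uniformly from
#' `height_range`, `d1_range` (along-row) and `d2_range` (cross-row)
#' unless explicit vectors are supplied; either way the generating
#' values are recorded in the returned ground truth. The crown is an
#' ellipsoid sitting on the trunk: vertical semi-axis
#' `(height - trunk_height) / 2`, horizontal semi-axes `d1/2`, `d2/2`.
#'
#' @param n_rows number of tree rows.
#' @param trees_per_row trees in each row.
#' @param tree_spacing,row_spacing planted spacings, meters.
#' @param height_range,d1_range,d2_range uniform sampling ranges (m) for
#'   per-tree height and crown diameters.
#' @param tree_height,d1,d2 optional explicit per-tree values (recycled).
#' @param trunk_height clear trunk below the crown, m.
#' @param trunk_radius trunk cylinder radius, m.
#' @param canopy_density crown surface sampling density, points per m^2
#'   of ellipsoid surface (a LiDAR samples surfaces, so the crown is
#'   sampled on its ellipsoid shell).
#' @param trunk_points points sampled on each trunk cylinder.
#' @param ground_density ground sampling density, points per m^2.
#' @param ground_margin ground extent beyond the planting rectangle, m.
#' @param ground_slope ground rise per meter of x (dz/dx).
#' @param noise_sigma isotropic Gaussian range-noise sd, m.
#' @param outlier_fraction sparse uniform outliers added, as a fraction
#'   of the clean point count; in `[0, 1)`.
#' @param seed integer RNG seed; identical specs give identical scenes.
#' @return An object of class `orchard_spec`.
#' @export
orchard_spec <- function(n_rows = 2, trees_per_row = 15,
                         tree_spacing = 3.2, row_spacing = 3.4,
                         height_range = c(2.5, 3.55),
                         d1_range = c(2.2, 2.6),
                         d2_range = c(2.3, 2.7),
                         tree_height = NULL, d1 = NULL, d2 = NULL,
                         trunk_height = 0.4, trunk_radius = 0.04,
                         canopy_density = 200, trunk_points = 80,
                         ground_density = 100, ground_margin = 2,
                         ground_slope = 0,
                         noise_sigma = 0.01, outlier_fraction = 0.01,
                         seed = 1) {
  if (n_rows < 1 || trees_per_row < 1) stop("orchard needs at least one tree")
  if (tree_spacing <= 0 || row_spacing <= 0) stop("spacings must be positive")
  if (trunk_height <= 0 || trunk_radius <= 0) stop("trunk dimensions must be positive")
  if (canopy_density <= 0 || ground_density <= 0) stop("densities must be positive")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("`outlier_fraction` must be in [0, 1)")
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative")
  structure(list(n_rows = n_rows, trees_per_row = trees_per_row,
                 tree_spacing = tree_spacing, row_spacing = row_spacing,
                 height_range = height_range, d1_range = d1_range,
                 d2_range = d2_range, tree_height = tree_height,
                 d1 = d1, d2 = d2,
                 trunk_height = trunk_height, trunk_radius = trunk_radius,
                 canopy_density = canopy_density, trunk_points = trunk_points,
                 ground_density = ground_density, ground_margin = ground_margin,
                 ground_slope = ground_slope, noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction, seed = as.integer(seed)),
            class = "orchard_spec")
}

# area-weighted uniform sampling on the surface of an ellipsoid with
# semi-axes (a, b, c): directions drawn on the unit sphere are accepted
# with probability proportional to the local area distortion
sample_ellipsoid_surface <- function(n, a, b, c_) {
  m_max <- max(b * c_, a * c_, a * b)
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    k <- max(64L, ceiling((n - nrow(out)) * 1.8))
    u <- matrix(stats::rnorm(3 * k), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    m <- sqrt((b * c_ * u[, 1])^2 + (a * c_ * u[, 2])^2 + (a * b * u[, 3])^2)
    keep <- stats::runif(k) <= m / m_max
    out <- rbind(out, cbind(a * u[keep, 1], b * u[keep, 2], c_ * u[keep, 3]))
  }
  out[seq_len(n), , drop = FALSE]
}

# Thomsen approximation to the ellipsoid surface area
ellipsoid_area <- function(a, b, c_) {
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c_^p + b^p * c_^p) / 3)^(1 / p)
}

#' Generate a labeled synthetic orchard point cloud
#'
#' Builds a scene from an [orchard_spec()]: a ground plane sample, one
#' trunk cylinder and one ellipsoid crown per tree, isotropic Gaussian
#' noise of sd `noise_sigma` on every scene point, plus uniform sparse
#' outliers in the scene bounding volume. Every point carries a label:
#' `0` = ground, `1..K` = tree id, `-1` = outlier. The returned ground
#' truth records the generating heights, crown diameters, canopy
#' reference heights and the planted spacings, so downstream estimates
#' can be validated exactly.
#'
#' @param spec an [orchard_spec()].
#' @return List with `cloud` (a [point_cloud()]), `truth` (an
#'   `orchard_truth`), `labels` (integer per point) and `spec`.
#' @examples
#' orch <- generate_orchard(orchard_spec(n_rows = 2, trees_per_row = 3,
#'                                       canopy_density = 40, seed = 7))
#' table(orch$labels)
#' @export
generate_orchard <- function(spec) {
  stopifnot(inherits(spec, "orchard_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_tree <- spec$n_rows * spec$trees_per_row
  if (n_tree < 1L) stop("orchard needs at least one tree")

  # planted layout: rows along X, tree t of row r at ((t-1)*ts, (r-1)*rs)
  layout <- expand.grid(position_in_row = seq_len(spec$trees_per_row),
                        row_index = seq_len(spec$n_rows))
  layout <- layout[order(layout$row_index, layout$position_in_row), ]
  px <- (layout$position_in_row - 1) * spec$tree_spacing
  py <- (layout$row_index - 1) * spec$row_spacing

  draw <- function(explicit, range) {
    if (!is.null(explicit)) rep_len(as.numeric(explicit), n_tree)
    else stats::runif(n_tree, range[1], range[2])
  }
  heights <- draw(spec$tree_height, spec$height_range)
  d1 <- draw(spec$d1, spec$d1_range)
  d2 <- draw(spec$d2, spec$d2_range)
  if (any(heights <= spec$trunk_height))
    stop("tree height must exceed trunk height")

  # ground rectangle around the planting
  gm <- spec$ground_margin
  gx <- c(min(px) - gm, max(px) + gm)
  gy <- c(min(py) - gm, max(py) + gm)
  n_ground <- max(1L, round(spec$ground_density * diff(gx) * diff(gy)))
  gxs <- stats::runif(n_ground, gx[1], gx[2])
  gys <- stats::runif(n_ground, gy[1], gy[2])
  ground <- cbind(gxs, gys, spec$ground_slope * gxs)

  pts <- list(ground)
  labels <- list(rep.int(0L, n_ground))
  for (t in seq_len(n_tree)) {
    base_z <- spec$ground_slope * px[t]
    crown_h <- heights[t] - spec$trunk_height
    a <- d1[t] / 2; b <- d2[t] / 2; c_ <- crown_h / 2
    n_can <- max(1L, round(spec$canopy_density * ellipsoid_area(a, b, c_)))
    crown <- sample_ellipsoid_surface(n_can, a, b, c_)
    crown <- sweep(crown, 2, c(px[t], py[t],
                               base_z + spec$trunk_height + c_), "+")
    # the trunk is sampled from 0.1 m upward: returns from the very
    # base are indistinguishable from ground hits in a real scan
    ang <- stats::runif(spec$trunk_points, 0, 2 * pi)
    tz <- stats::runif(spec$trunk_points, min(0.1, spec$trunk_height / 2),
                       spec$trunk_height)
    trunk <- cbind(px[t] + spec$trunk_radius * cos(ang),
                   py[t] + spec$trunk_radius * sin(ang),
                   base_z + tz)
    tree_pts <- rbind(crown, trunk)
    if (nrow(tree_pts) < 50L)
      warning(sprintf("tree %d sampled with only %d points; increase canopy_density",
                      t, nrow(tree_pts)))
    pts[[length(pts) + 1L]] <- tree_pts
    labels[[length(labels) + 1L]] <- rep.int(t, nrow(tree_pts))
  }

  clean <- do.call(rbind, pts)
  lab <- unlist(labels, use.names = FALSE)
  n_clean <- nrow(clean)
  if (spec$noise_sigma > 0)
    clean <- clean + matrix(stats::rnorm(3 * n_clean, sd = spec$noise_sigma),
                            ncol = 3)

  n_out <- round(spec$outlier_fraction * n_clean)
  if (n_out > 0L) {
    zmax <- max(heights) + max(abs(spec$ground_slope * gx)) + 0.5
    outl <- cbind(stats::runif(n_out, gx[1], gx[2]),
                  stats::runif(n_out, gy[1], gy[2]),
                  stats::runif(n_out, 0, zmax))
    clean <- rbind(clean, outl)
    lab <- c(lab, rep.int(-1L, n_out))
  }

  trees <- data.frame(tree_id = seq_len(n_tree),
                      row_index = layout$row_index,
                      position_in_row = layout$position_in_row,
                      height_m = heights, d1_m = d1, d2_m = d2,
                      ht1_m = heights, hs1_m = spec$trunk_height,
                      ht2_m = heights, hs2_m = spec$trunk_height,
                      x_m = px, y_m = py)
  truth <- orchard_truth(trees, tree_spacing = spec$tree_spacing,
                         row_spacing = spec$row_spacing)

  list(cloud = point_cloud(clean), truth = truth, labels = lab, spec = spec)
}

#' Write an orchard scene to disk
#'
#' Emits the cloud (any supported format), the ground-truth CSV and a
#' per-point label CSV next to it.
#'
#' @param orchard result of [generate_orchard()].
#' @param cloud_path output cloud file (format from extension).
#' @param truth_path output ground-truth CSV.
#' @param labels_path output labels CSV (single `label` column).
#' @return Invisibly, the three paths.
#' @export
write_orchard <- function(orchard, cloud_path, truth_path, labels_path) {
  write_point_cloud(orchard$cloud, cloud_path)
  write_ground_truth(orchard$truth, truth_path)
  utils::write.csv(data.frame(label = orchard$labels), labels_path,
                   row.names = FALSE)
  invisible(c(cloud_path, truth_path, labels_path))
}
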