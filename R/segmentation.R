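#' Fit the ground plane with RANSAC
#'
#' Minimal 3-point samples are drawn from the cloud; the candidate plane
#' with the most inliers at `dist_threshold` wins (ties keep the
#' earliest draw) and is refit by total least squares on its inliers.
#' The refit normal is oriented with a non-negative Z component so that
#' "above the plane" means towards the canopy.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @param dist_threshold inlier distance to the plane, meters.
#' @param n_iterations number of random minimal samples.
#' @param seed optional integer; when given the sampling is reproducible.
#' @return An object of class `plane_model`: unit `normal` (a, b, c),
#'   `offset` d of the plane a x + b y + c z + d = 0, the threshold, and
#'   the inlier index vector.
#' @export
fit_ground_plane <- function(cloud, dist_threshold = 0.05,
                             n_iterations = 1000, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n < 3L) stop("plane fit needs at least 3 points")
  if (!is.null(seed)) set.seed(seed)
  samples <- t(replicate(n_iterations, sample.int(n, 3L)))
  best <- .ransac_plane_score(cloud$points, samples, dist_threshold)
  if (!isTRUE(best$ok))
    stop("degenerate cloud: all RANSAC samples were collinear")
  normal <- best$normal
  offset <- best$offset
  # refit by total least squares on the consensus set
  d0 <- abs(cloud$points %*% normal + offset)
  inl <- which(d0 <= dist_threshold)
  if (length(inl) >= 3L) {
    P <- cloud$points[inl, , drop = FALSE]
    ctr <- colMeans(P)
    sv <- svd(sweep(P, 2, ctr), nu = 0)
    cand <- sv$v[, 3]
    if (sum(abs(cand)) > 0) {
      normal <- cand / sqrt(sum(cand^2))
      offset <- -sum(normal * ctr)
    }
  }
  if (normal[3] < 0) { normal <- -normal; offset <- -offset }
  dist <- as.numeric(cloud$points %*% normal + offset)
  inliers <- which(abs(dist) <= dist_threshold)
  structure(list(normal = as.numeric(normal), offset = as.numeric(offset),
                 dist_threshold = dist_threshold, inliers = inliers,
                 n_iterations = n_iterations),
            class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("plane_model: %.4f x + %.4f y + %.4f z + %.4f = 0 (%d inliers at %.3f m)\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              length(x$inliers), x$dist_threshold))
  invisible(x)
}

# signed distance of each point to a plane (positive = above)
plane_distance <- function(cloud, plane) {
  as.numeric(cloud$points %*% plane$normal + plane$offset)
}

#' Remove ground points given a fitted plane
#'
#' Keeps the points whose signed distance above the plane exceeds
#' `clearance`, which defaults to the plane's inlier threshold;
#' everything at or below it (ground returns and near-ground clutter)
#' is dropped. A larger clearance (e.g. the trunk height) is useful
#' before crown clustering, where low stray points would otherwise
#' bridge neighbouring trees.
#'
#' @param cloud a [point_cloud()].
#' @param plane a `plane_model` from [fit_ground_plane()].
#' @param clearance minimum height above the plane to keep, meters.
#' @return List with `cloud` (above-ground points) and `keep`, the
#'   logical retention mask over the input.
#' @export
remove_ground <- function(cloud, plane, clearance = plane$dist_threshold) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(plane, "plane_model"))
  if (n_points(cloud) == 0L)
    return(list(cloud = cloud, keep = logical(0)))
  keep <- plane_distance(cloud, plane) > clearance
  list(cloud = subset_cloud(cloud, keep), keep = keep)
}

#' Crop a cloud to an axis-aligned region of interest
#'
#' @param cloud a [point_cloud()].
#' @param box an [roi_box()].
#' @return List with `cloud` (in-box points) and their `indices` in the
#'   input cloud.
#' @export
crop_roi <- function(cloud, box) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!inherits(box, "roi_box")) stop("`box` must be an roi_box")
  if (n_points(cloud) == 0L)
    return(list(cloud = cloud, indices = integer(0)))
  idx <- kd_range_query(kd_tree(cloud), box)
  list(cloud = subset_cloud(cloud, idx), indices = idx)
}

#' DBSCAN clustering in the horizontal plane
#'
#' Standard density-based clustering: a core point has at least
#' `min_pts` points (itself included) within `eps`; clusters are the
#' connected components of core points plus their border points; the
#' rest is noise (label -1). The Z coordinate is ignored by default
#' because trees separate in the x-y plane. Border points reachable from
#' two clusters join the first-visited one (points are visited in index
#' order), which makes the labeling deterministic.
#'
#' @param cloud a [point_cloud()] or an n x 2 / n x 3 coordinate matrix.
#' @param eps neighborhood radius in meters.
#' @param min_pts minimum neighborhood size for a core point.
#' @param use_z include Z in the distance (default `FALSE`).
#' @return Integer labels, one per point: -1 for noise, 1.. for clusters
#'   in order of discovery.
#' @export
dbscan_cluster <- function(cloud, eps, min_pts, use_z = FALSE) {
  if (eps <= 0) stop("`eps` must be positive")
  if (min_pts < 1) stop("`min_pts` must be at least 1")
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else as.matrix(cloud)
  if (ncol(pts) == 2L) pts <- cbind(pts, 0)
  stopifnot(ncol(pts) == 3L)
  storage.mode(pts) <- "double"
  if (!use_z) pts[, 3] <- 0
  if (nrow(pts) == 0L) return(integer(0))
  .dbscan_labels(pts, eps, as.integer(min_pts))
}

# 1D DBSCAN on a numeric vector, O(n log n) via sorting and a sliding
# window: core = at least min_pts values within eps (self included);
# clusters = chains of core points with consecutive core gaps <= eps;
# non-core values within eps of a core join its cluster (ties go to
# the lower-value cluster), the rest are noise (-1). Clusters are
# numbered 1.. by increasing value.
dbscan_1d <- function(v, eps, min_pts = 1L) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  o <- order(v)
  sv <- v[o]
  lo <- findInterval(sv - eps, sv) + 1L  # first index with value >= sv - eps
  hi <- findInterval(sv + eps, sv)       # last index with value <= sv + eps
  core <- (hi - lo + 1L) >= min_pts
  lab_sorted <- rep.int(-1L, n)
  ci <- which(core)
  if (length(ci) > 0L) {
    new_cluster <- c(TRUE, diff(sv[ci]) > eps)
    lab_sorted[ci] <- cumsum(new_cluster)
    # border points: nearest core neighbour within eps, lower side first
    bi <- which(!core)
    if (length(bi) > 0L) {
      prev_core <- findInterval(bi, ci)              # last core index <= bi
      ok_prev <- prev_core >= 1L
      ok_prev[ok_prev] <- sv[bi[ok_prev]] - sv[ci[prev_core[ok_prev]]] <= eps
      next_core <- prev_core + 1L                    # first core index > bi
      ok_next <- next_core <= length(ci)
      ok_next[ok_next] <- sv[ci[next_core[ok_next]]] - sv[bi[ok_next]] <= eps
      lab_sorted[bi[ok_prev]] <- lab_sorted[ci[prev_core[ok_prev]]]
      fill <- !ok_prev & ok_next
      lab_sorted[bi[fill]] <- lab_sorted[ci[next_core[fill]]]
    }
  }
  labels <- integer(n)
  labels[o] <- lab_sorted
  labels
}

#' Cluster an above-ground cloud into rows and individual trees
#'
#' Two-stage grouping: rows are found first by 1D DBSCAN on the
#' cross-row (y) coordinate (same `min_pts`, radius `row_eps`), then
#' each row is clustered in the x-y plane with DBSCAN at a tree-scale
#' `eps`. Rows are numbered by
#' increasing mean y, trees within a row by increasing x, and tree ids
#' run sequentially across rows. With `strategy = "single-stage"` the
#' row stage is skipped and trees are clustered directly in x-y, with
#' rows inferred afterwards by 1D clustering of the tree centroids' y
#' values.
#'
#' @param cloud a ground-free [point_cloud()].
#' @param eps DBSCAN radius for the tree stage, meters.
#' @param min_pts DBSCAN core threshold (both stages).
#' @param row_eps DBSCAN radius for the row stage (on y), meters.
#' @param strategy `"rows-then-trees"` (default) or `"single-stage"`.
#' @return An object of class `tree_clusters`: `labels` (per-point tree
#'   id, -1 = noise) and a `trees` data frame with `tree_id`, `row_id`,
#'   `position_in_row`, centroid `x`, `y`, `z` and `n_points`.
#' @export
cluster_trees <- function(cloud, eps = 0.4, min_pts = 10, row_eps = eps,
                          strategy = c("rows-then-trees", "single-stage")) {
  stopifnot(inherits(cloud, "point_cloud"))
  strategy <- match.arg(strategy)
  n <- n_points(cloud)
  if (n == 0L) stop("cannot cluster an empty cloud")
  pts <- cloud$points

  if (strategy == "rows-then-trees") {
    ylab <- dbscan_1d(pts[, 2], eps = row_eps, min_pts = min_pts)
    row_ids <- sort(unique(ylab[ylab > 0]))
    if (length(row_ids) == 0L)
      stop("segmentation error: no tree rows found (eps/min_pts too strict?)")
    # order rows by mean y
    row_means <- vapply(row_ids, function(r) mean(pts[ylab == r, 2]), numeric(1))
    row_order <- row_ids[order(row_means)]
    labels <- rep.int(-1L, n)
    trees <- list()
    tid <- 0L
    for (ri in seq_along(row_order)) {
      sel <- which(ylab == row_order[ri])
      sub <- pts[sel, , drop = FALSE]
      tlab <- dbscan_cluster(sub, eps = eps, min_pts = min_pts)
      t_ids <- sort(unique(tlab[tlab > 0]))
      if (length(t_ids) == 0L) next
      xmeans <- vapply(t_ids, function(k) mean(sub[tlab == k, 1]), numeric(1))
      for (k in t_ids[order(xmeans)]) {
        tid <- tid + 1L
        members <- sel[tlab == k]
        labels[members] <- tid
        ctr <- colMeans(pts[members, , drop = FALSE])
        trees[[tid]] <- data.frame(tree_id = tid, row_id = ri,
                                   position_in_row = sum(vapply(trees, function(t)
                                     t$row_id == ri, logical(1))) + 1L,
                                   x = ctr[1], y = ctr[2], z = ctr[3],
                                   n_points = length(members))
      }
    }
  } else {
    tlab <- dbscan_cluster(cloud, eps = eps, min_pts = min_pts)
    t_ids <- sort(unique(tlab[tlab > 0]))
    if (length(t_ids) == 0L)
      stop("segmentation error: no trees found (eps/min_pts too strict?)")
    ctrs <- t(vapply(t_ids, function(k)
      colMeans(pts[tlab == k, , drop = FALSE]), numeric(3)))
    # infer rows by 1D clustering of centroid y with a row-scale radius
    rl <- dbscan_cluster(cbind(ctrs[, 2], 0, 0), eps = row_eps, min_pts = 1)
    row_ids <- sort(unique(rl))
    row_means <- vapply(row_ids, function(r) mean(ctrs[rl == r, 2]), numeric(1))
    row_rank <- match(rl, row_ids[order(row_means)])
    ord <- order(row_rank, ctrs[, 1])
    labels <- rep.int(-1L, n)
    trees <- list()
    pos <- integer(max(row_rank))
    for (j in seq_along(ord)) {
      k <- t_ids[ord[j]]
      members <- which(tlab == k)
      labels[members] <- j
      ri <- row_rank[ord[j]]
      pos[ri] <- pos[ri] + 1L
      trees[[j]] <- data.frame(tree_id = j, row_id = ri,
                               position_in_row = pos[ri],
                               x = ctrs[ord[j], 1], y = ctrs[ord[j], 2],
                               z = ctrs[ord[j], 3],
                               n_points = length(members))
    }
  }

  if (length(trees) == 0L)
    stop("segmentation error: no trees found (eps/min_pts too strict?)")
  trees <- do.call(rbind, trees)
  rownames(trees) <- NULL
  structure(list(labels = labels, trees = trees, eps = eps,
                 min_pts = min_pts, strategy = strategy),
            class = "tree_clusters")
}

#' @export
print.tree_clusters <- function(x, ...) {
  cat(sprintf("tree_clusters: %d trees in %d row(s); %d noise point(s)\n",
              nrow(x$trees), length(unique(x$trees$row_id)),
              sum(x$labels == -1L)))
  invisible(x)
}
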