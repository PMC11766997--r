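test_that("RANSAC recovers exact planes", {
  set.seed(1)
  ground <- cbind(runif(200, 0, 10), runif(200, 0, 10), 0)
  canopy <- cbind(runif(5, 0, 10), runif(5, 0, 10), runif(5, 1, 3))
  pc <- point_cloud(rbind(ground, canopy))
  pl <- fit_ground_plane(pc, dist_threshold = 0.02, seed = 7)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-6)
  expect_true(all(seq_len(200) %in% pl$inliers))
  expect_false(any(201:205 %in% pl$inliers))

  # sloped ground z = 0.1 x has normal prop. to (-0.1, 0, 1)
  sloped <- cbind(ground[, 1], ground[, 2], 0.1 * ground[, 1])
  pc <- point_cloud(rbind(sloped, canopy))
  pl <- fit_ground_plane(pc, dist_threshold = 0.02, seed = 7)
  expected <- c(-0.1, 0, 1) / sqrt(1.01)
  expect_equal(pl$normal, expected, tolerance = 1e-6)
})

test_that("RANSAC is seeded-reproducible and degenerate inputs error", {
  pc <- tiny_orchard(seed = 2, sigma = 0.01, outliers = 0.01)$cloud
  p1 <- fit_ground_plane(pc, seed = 5)
  p2 <- fit_ground_plane(pc, seed = 5)
  expect_identical(p1$normal, p2$normal)
  expect_identical(p1$inliers, p2$inliers)

  expect_error(fit_ground_plane(point_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "at least 3")
  collinear <- point_cloud(cbind(1:10, 1:10, 1:10))
  expect_error(fit_ground_plane(collinear, seed = 1), "collinear")

  # inlier count is non-decreasing in the distance threshold
  counts <- vapply(c(0.01, 0.05, 0.1, 0.5), function(th)
    length(fit_ground_plane(pc, dist_threshold = th, seed = 3)$inliers),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ground removal on a noiseless orchard is label-exact", {
  orch <- tiny_orchard(seed = 13, sigma = 0, outliers = 0)
  pl <- fit_ground_plane(orch$cloud, dist_threshold = 0.05, seed = 1)
  res <- remove_ground(orch$cloud, pl)
  expect_identical(res$keep, orch$labels > 0L)

  allground <- point_cloud(cbind(runif(100), runif(100), 0))
  pl <- fit_ground_plane(allground, dist_threshold = 0.02, seed = 1)
  expect_equal(n_points(remove_ground(allground, pl)$cloud), 0L)
})

test_that("ground removal misclassifies <1% of points under noise", {
  orch <- tiny_orchard(seed = 17, sigma = 0.01, outliers = 0)
  pl <- fit_ground_plane(orch$cloud, dist_threshold = 0.05, seed = 1)
  res <- remove_ground(orch$cloud, pl)
  ground_kept <- sum(res$keep & orch$labels == 0L) / sum(orch$labels == 0L)
  tree_lost <- sum(!res$keep & orch$labels > 0L) / sum(orch$labels > 0L)
  expect_lt(ground_kept, 0.01)
  expect_lt(tree_lost, 0.01)
})

test_that("crop_roi returns exactly the in-box points", {
  pc <- random_cloud(300, seed = 3)
  lo <- c(0.2, 0.1, 0.3); hi <- c(0.7, 0.9, 0.8)
  res <- crop_roi(pc, roi_box(lo, hi))
  expect_equal(res$indices, range_oracle(pc$points, lo, hi))
  expect_equal(n_points(crop_roi(pc, roi_box(c(0, 0, 0), c(1, 1, 1)))$cloud),
               300L)
  expect_error(crop_roi(pc, "box"), "roi_box")
})

test_that("DBSCAN handles the constructed cases", {
  set.seed(5)
  blob <- function(cx, cy, n = 20) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  two <- rbind(blob(0, 0), blob(3, 0))
  lab <- dbscan_cluster(two, eps = 0.5, min_pts = 4)
  expect_equal(sort(unique(lab)), 1:2)
  expect_equal(sum(lab == -1L), 0L)
  expect_equal(length(unique(lab[1:20])), 1L)

  one <- rbind(blob(0, 0), c(10, 10))
  lab <- dbscan_cluster(one, eps = 0.5, min_pts = 4)
  expect_equal(lab[21], -1L)
})

test_that("DBSCAN equals the brute-force oracle, identically", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- cbind(runif(200, 0, 2), runif(200, 0, 2), 0)
    got <- dbscan_cluster(pts, eps = 0.2, min_pts = 5)
    expect_identical(got, dbscan_oracle(pts, eps = 0.2, min_pts = 5))
  }
})

test_that("DBSCAN partition is invariant to point order", {
  set.seed(31)
  pts <- cbind(runif(250, 0, 2), runif(250, 0, 2), 0)
  lab <- dbscan_cluster(pts, eps = 0.2, min_pts = 5)
  perm <- sample(250)
  lab2 <- dbscan_cluster(pts[perm, ], eps = 0.2, min_pts = 5)
  # core-point partition agrees up to relabeling; compare via pair matrix
  same1 <- outer(lab, lab, "==") & lab > 0
  same2p <- outer(lab2, lab2, "==") & lab2 > 0
  same2 <- same2p[order(perm), order(perm)]
  core_mismatch <- mean(same1 != same2)
  expect_lt(core_mismatch, 0.01) # border-point ties may differ by design
  expect_equal(sort(table(lab[lab > 0])), sort(table(lab2[lab2 > 0])))
})

test_that("cluster_trees recovers the planted layout noiselessly", {
  orch <- tiny_orchard(seed = 23, sigma = 0, outliers = 0)
  pl <- fit_ground_plane(orch$cloud, dist_threshold = 0.05, seed = 1)
  above <- remove_ground(orch$cloud, pl, clearance = 0.3)
  cl <- cluster_trees(above$cloud, eps = 0.4, min_pts = 10)
  expect_equal(nrow(cl$trees), 6L)
  expect_equal(sort(unique(cl$trees$row_id)), 1:2)
  expect_equal(cl$trees$position_in_row, rep(1:3, 2))
  # tree ids follow the generator's row-major order, so labels agree
  truth_lab <- orch$labels[above$keep]
  agree <- mean(cl$labels == truth_lab)
  expect_equal(agree, 1)
})

test_that("single tree clusters as one row, one tree", {
  orch <- generate_orchard(orchard_spec(n_rows = 1, trees_per_row = 1,
                                        noise_sigma = 0,
                                        outlier_fraction = 0, seed = 3))
  keep <- orch$cloud$points[, 3] > 0.3
  cl <- cluster_trees(point_cloud(orch$cloud$points[keep, ]),
                      eps = 0.4, min_pts = 10)
  expect_equal(nrow(cl$trees), 1L)
  expect_equal(cl$trees$row_id, 1L)
})

test_that("noisy orchard point-to-tree assignment is at least 95% right", {
  orch <- generate_orchard(orchard_spec(n_rows = 2, trees_per_row = 6,
                                        noise_sigma = 0.01,
                                        outlier_fraction = 0.01, seed = 29))
  ror <- radius_outlier_removal(orch$cloud, 4, 0.2)
  pl <- fit_ground_plane(ror$cloud, dist_threshold = 0.05, seed = 1)
  above <- remove_ground(ror$cloud, pl, clearance = 0.3)
  cl <- cluster_trees(above$cloud, eps = 0.4, min_pts = 10)
  expect_equal(nrow(cl$trees), 12L)
  truth_lab <- orch$labels[!ror$removed][above$keep]
  tree_pts <- truth_lab > 0L
  agree <- mean(cl$labels[tree_pts] == truth_lab[tree_pts])
  expect_gte(agree, 0.95)
})
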