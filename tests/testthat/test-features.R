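test_that("tree height is the z extent", {
  pc <- point_cloud(cbind(0, 0, c(0.45, 1.2, 3.50)))
  h <- tree_height(pc)
  expect_equal(h$h_tree, 3.05)
  expect_equal(h$h_max, 3.50)
  expect_equal(tree_height(point_cloud(rbind(c(1, 2, 3))))$h_tree, 0)
  expect_error(tree_height(point_cloud(matrix(numeric(0), ncol = 3))),
               "empty")
})

test_that("bounding box equals per-axis min/max", {
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  bb <- bounding_box(cube)
  expect_equal(bb$volume, 1)

  expect_warning(bb <- bounding_box(point_cloud(cbind(runif(10), runif(10), 0))),
                 "flat")
  expect_equal(bb$volume, 0)

  set.seed(6)
  pts <- cbind(runif(500, 0, 2), runif(500, 0, 1), runif(500, 0, 3))
  bb <- bounding_box(point_cloud(pts))
  expect_equal(unname(bb$min), unname(apply(pts, 2, min)))
  expect_equal(unname(bb$max), unname(apply(pts, 2, max)))
  expect_equal(bb$volume, prod(apply(pts, 2, max) - apply(pts, 2, min)))
})

test_that("canopy bounding-box volume substitutes the measured width", {
  pts <- rbind(c(0, 0, 0), c(2, 0.8, 3)) # extents 2 x 0.8 x 3
  pc <- point_cloud(pts)
  cv <- canopy_volume_bbox(pc)
  expect_equal(cv$volume, 4.8)
  expect_false(cv$width_adjusted)

  cv <- canopy_volume_bbox(pc, measured_width = 1.5)
  expect_equal(cv$volume, 9.0)
  expect_true(cv$width_adjusted)
  expect_error(canopy_volume_bbox(pc, measured_width = 0), "positive")

  # monotone non-decreasing in the substituted width
  vols <- vapply(seq(0.1, 3, by = 0.2),
                 function(w) canopy_volume_bbox(pc, w)$volume, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("manual canopy volume has the ellipsoid closed forms", {
  expect_equal(manual_canopy_volume(2, 2, 2, 0, 2, 0), 4 * pi / 3)
  expect_equal(manual_canopy_volume(0, 2, 2, 0, 2, 0), 0)
  expect_equal(manual_canopy_volume(3, 2, 2.4, 0, 2.6, 0), 2.5 * pi)
  # reduces to (pi/6) d1 d2 d3 when both vertical extents equal d3
  for (i in 1:10) {
    set.seed(i)
    d <- runif(3, 0.5, 4)
    expect_equal(manual_canopy_volume(d[1], d[2], d[3] + 1, 1, d[3] + 1, 1),
                 pi / 6 * prod(d), tolerance = 1e-12)
  }
  expect_error(manual_canopy_volume(-1, 2, 2, 0, 2, 0), "non-negative")
  expect_error(manual_canopy_volume(1, 2, 1, 2, 2, 0), "Ht >= Hs")
})

test_that("noiseless ellipsoid crown: bbox approaches the axis box and
           the manual volume is exactly pi/6 of it", {
  orch <- generate_orchard(orchard_spec(
    n_rows = 1, trees_per_row = 1, tree_height = 3.0, d1 = 2.4, d2 = 2.6,
    noise_sigma = 0, outlier_fraction = 0, canopy_density = 600, seed = 8))
  crown <- orch$cloud$points[orch$labels == 1 & orch$cloud$points[, 3] > 0.41, ]
  cv <- canopy_volume_bbox(point_cloud(crown))
  box <- 2.4 * 2.6 * (3.0 - 0.4)
  expect_equal(cv$volume, box, tolerance = 0.02)
  tr <- orch$truth$trees
  manual <- manual_canopy_volume(tr$d1_m, tr$d2_m, tr$ht1_m, tr$hs1_m,
                                 tr$ht2_m, tr$hs2_m)
  expect_equal(manual, pi / 6 * box, tolerance = 1e-12)
})

test_that("centroid is the coordinate-wise mean", {
  expect_equal(cloud_centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(4)
  pts <- matrix(runif(3000), ncol = 3)
  expect_equal(unname(cloud_centroid(pts)), unname(colMeans(pts)),
               tolerance = 1e-12)
  perm <- sample(1000)
  expect_equal(cloud_centroid(pts[perm, ]), cloud_centroid(pts))
  expect_error(cloud_centroid(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("spacing is the planar distance between consecutive centroids", {
  trees <- data.frame(tree_id = 1:2, row_id = 1, position_in_row = 1:2,
                      x = c(0, 3), y = c(0, 4))
  sp <- spacing(trees)
  expect_equal(sp$tree_spacing$distance, 5)

  trees$x <- 0; trees$y <- 0
  expect_equal(spacing(trees)$tree_spacing$distance, 0)
  expect_error(spacing(trees[1, ]), "at least 2")
})

test_that("row spacing supports both pairing modes", {
  trees <- data.frame(tree_id = 1:4, row_id = rep(1:2, each = 2),
                      position_in_row = rep(1:2, 2),
                      x = c(0, 3, 0.5, 3.5), y = c(0, 0, 3.4, 3.4))
  rc <- spacing(trees, row_method = "row-centroid")
  expect_equal(rc$row_spacing$distance, sqrt(0.5^2 + 3.4^2))
  tt <- spacing(trees, row_method = "tree-to-tree")
  expect_equal(tt$row_spacing$distance, sqrt(0.5^2 + 3.4^2))
})

test_that("height and spacing are rigid-motion invariant", {
  orch <- tiny_orchard(seed = 37, sigma = 0, outliers = 0)
  tr <- subset_pc <- orch$cloud$points[orch$labels == 1, ]
  h0 <- tree_height(point_cloud(tr))$h_tree
  shifted <- sweep(tr, 2, c(5, -3, 2), "+")
  expect_equal(tree_height(point_cloud(shifted))$h_tree, h0, tolerance = 1e-12)

  trees <- data.frame(tree_id = 1:3, row_id = 1, position_in_row = 1:3,
                      x = c(0, 3.2, 6.4), y = c(0, 0.1, -0.1))
  base <- spacing(trees)$tree_spacing$distance
  th <- 33 * pi / 180
  rot <- cbind(trees$x * cos(th) - trees$y * sin(th),
               trees$x * sin(th) + trees$y * cos(th))
  trees2 <- transform(trees, x = rot[, 1] + 7, y = rot[, 2] - 2)
  expect_equal(spacing(trees2)$tree_spacing$distance, base, tolerance = 1e-12)
})

test_that("noiseless orchard spacing is recovered to sampling error", {
  orch <- tiny_orchard(seed = 41, sigma = 0, outliers = 0)
  pl <- fit_ground_plane(orch$cloud, dist_threshold = 0.05, seed = 1)
  above <- remove_ground(orch$cloud, pl, clearance = 0.3)
  cl <- cluster_trees(above$cloud, eps = 0.4, min_pts = 10)
  sp <- spacing(cl$trees)
  expect_true(all(abs(sp$tree_spacing$distance - 3.2) <= 0.02))
  expect_true(all(abs(sp$row_spacing$distance - 3.4) <= 0.02))
})
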