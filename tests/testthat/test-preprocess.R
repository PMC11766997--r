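test_that("two-phase rotation matches the printed conventions", {
  # counterclockwise Z: x-axis goes to y-axis
  pc <- point_cloud(rbind(c(1, 0, 0)))
  out <- transform_coordinates(pc, rotation_spec(theta = 90, phi = 0))
  expect_equal(as.numeric(out$points), c(0, 1, 0), tolerance = 1e-12)

  # clockwise Y (the printed matrix): x-axis goes to z-axis
  out <- transform_coordinates(pc, rotation_spec(theta = 0, phi = 90))
  expect_equal(as.numeric(out$points), c(0, 0, 1), tolerance = 1e-12)

  # standard counterclockwise Y instead sends x to -z
  out <- transform_coordinates(pc, rotation_spec(theta = 0, phi = 90,
                                                 y_clockwise = FALSE))
  expect_equal(as.numeric(out$points), c(0, 0, -1), tolerance = 1e-12)

  # identity case
  pc <- random_cloud(50, seed = 1)
  out <- transform_coordinates(pc, rotation_spec(0, 0))
  expect_equal(out$points, pc$points)
})

test_that("rotation matrices are orthonormal and distance-preserving", {
  set.seed(42)
  for (i in 1:20) {
    th <- runif(1, -180, 180); ph <- runif(1, -180, 180)
    for (R in list(rotation_matrix_z(th), rotation_matrix_y(ph),
                   rotation_matrix_y(ph, clockwise = FALSE))) {
      expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
    pc <- random_cloud(40, seed = i)
    out <- transform_coordinates(pc, rotation_spec(th, ph))
    expect_lt(max(abs(dist(out$points) - dist(pc$points))), 1e-9)
  }
})

test_that("radius outlier removal keeps dense points and drops isolates", {
  # 50 coincident points easily exceed 32 mutual neighbors; a point 1 m
  # away has none
  pts <- rbind(matrix(0, nrow = 50, ncol = 3), c(1, 0, 0))
  res <- radius_outlier_removal(point_cloud(pts), min_neighbors = 32,
                                radius = 0.01)
  expect_equal(res$removed, c(rep(FALSE, 50), TRUE))
  expect_equal(n_points(res$cloud), 50L)

  # pigeonhole: 10 points can never have 32 neighbors
  res <- radius_outlier_removal(random_cloud(10, seed = 1),
                                min_neighbors = 32, radius = 10)
  expect_true(all(res$removed))

  empty <- point_cloud(matrix(numeric(0), ncol = 3))
  res <- radius_outlier_removal(empty, 5, 0.1)
  expect_equal(n_points(res$cloud), 0L)
})

test_that("radius outlier removal matches the brute-force oracle", {
  for (seed in 1:8) {
    pc <- random_cloud(500, seed = seed)
    res <- radius_outlier_removal(pc, min_neighbors = 5, radius = 0.1)
    oracle <- ror_oracle_counts(pc$points, 0.1)
    expect_equal(res$neighbor_counts, as.integer(oracle))
    expect_equal(res$removed, unname(oracle < 5))
  }
})

test_that("radius outlier removal is order-independent", {
  pc <- random_cloud(300, seed = 9)
  perm <- sample(300)
  res1 <- radius_outlier_removal(pc, 5, 0.1)
  res2 <- radius_outlier_removal(point_cloud(pc$points[perm, ]), 5, 0.1)
  expect_equal(res2$removed, res1$removed[perm])
})

test_that("voxel downsampling returns per-voxel centroids", {
  # four points in one 0.01 cell collapse to their centroid
  pts <- rbind(c(0.001, 0.001, 0.001), c(0.009, 0.002, 0.003),
               c(0.004, 0.008, 0.001), c(0.002, 0.003, 0.009))
  out <- voxel_downsample(point_cloud(pts), 0.01)
  expect_equal(n_points(out), 1L)
  expect_equal(as.numeric(out$points), colMeans(pts))

  # two occupied cells stay two points
  out <- voxel_downsample(point_cloud(rbind(c(0.005, 0, 0), c(0.015, 0, 0))),
                          0.01)
  expect_equal(n_points(out), 2L)
})

test_that("voxel downsampling matches the hashing oracle", {
  for (seed in 1:5) {
    pc <- random_cloud(1000, seed = seed)
    out <- voxel_downsample(pc, 0.05)
    oracle <- voxel_oracle(pc$points, 0.05)
    expect_equal(n_points(out), nrow(oracle))
    got <- out$points[order(out$points[, 1], out$points[, 2], out$points[, 3]), ]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    expect_lte(n_points(out), n_points(pc))
  }
})

test_that("kd range queries equal a linear scan", {
  # unit-cube corners: the [0, 0.5]^3 box holds exactly the origin corner
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tree <- kd_tree(corners)
  expect_equal(kd_range_query(tree, roi_box(c(0, 0, 0), c(0.5, 0.5, 0.5))), 1L)
  expect_equal(kd_range_query(tree, roi_box(c(-1, -1, -1), c(2, 2, 2))), 1:8)
  expect_error(roi_box(c(1, 0, 0), c(0, 1, 1)), "degenerate")

  for (seed in 1:10) {
    pc <- random_cloud(300, seed = seed)
    tree <- kd_tree(pc)
    set.seed(seed + 100)
    lo <- runif(3, 0, 0.6); hi <- lo + runif(3, 0.05, 0.4)
    expect_equal(kd_range_query(tree, roi_box(lo, hi)),
                 range_oracle(pc$points, lo, hi))
  }
})

test_that("kd radius queries equal a linear scan", {
  for (seed in 1:5) {
    pc <- random_cloud(400, seed = seed)
    tree <- kd_tree(pc)
    q <- runif(3)
    got <- kd_radius_query(tree, q, 0.25)
    d <- sqrt(colSums((t(pc$points) - q)^2))
    expect_equal(got, which(d <= 0.25))
  }
})

test_that("statistical filter removes points lifted off a surface", {
  set.seed(21)
  sheet <- cbind(runif(800, 0, 2), runif(800, 0, 2), 0)
  lifted <- c(1, 1, 0.4)
  pc <- point_cloud(rbind(sheet, lifted))
  res <- statistical_outlier_removal(pc, k = 10, alpha = 2)
  expect_true(res$removed[801])
  expect_lt(mean(res$removed[1:800]), 0.05)
})
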