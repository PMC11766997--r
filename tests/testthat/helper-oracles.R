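# Brute-force oracles, deliberately independent of the package's
# spatial index: every neighborhood is found by a full distance scan.

random_cloud <- function(n, lo = 0, hi = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_cloud(matrix(runif(3 * n, lo, hi), ncol = 3))
}

# neighbor counts (self excluded) by full pairwise distances
ror_oracle_counts <- function(pts, radius) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  rowSums(d <= radius)
}

# occupied-voxel centroids by string hashing of floor(p / voxel)
voxel_oracle <- function(pts, voxel) {
  key <- apply(floor(pts / voxel), 1, paste, collapse = "|")
  centroids <- lapply(split(seq_len(nrow(pts)), key),
                      function(i) colMeans(pts[i, , drop = FALSE]))
  m <- do.call(rbind, centroids)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

range_oracle <- function(pts, lo, hi) {
  which(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
        pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
        pts[, 3] >= lo[3] & pts[, 3] <= hi[3])
}

# textbook DBSCAN with the same deterministic visiting order as the
# implementation (index order; sorted neighbor lists; FIFO expansion),
# but all neighborhoods from an O(n^2) distance matrix
dbscan_oracle <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  nbhd <- lapply(seq_len(n), function(i) which(d[i, ] <= eps)) # self included
  label <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (label[i] != 0L) next
    if (length(nbhd[[i]]) < min_pts) { label[i] <- -1L; next }
    cid <- cid + 1L
    label[i] <- cid
    seeds <- nbhd[[i]]
    while (length(seeds) > 0L) {
      q <- seeds[1]
      seeds <- seeds[-1]
      if (label[q] == cid || label[q] > 0L) next
      was_noise <- label[q] == -1L
      label[q] <- cid
      if (was_noise) next
      if (length(nbhd[[q]]) >= min_pts)
        seeds <- c(seeds, nbhd[[q]][label[nbhd[[q]]] <= 0L])
    }
  }
  label
}

# small noiseless orchard used across tests
tiny_orchard <- function(seed = 7, sigma = 0, outliers = 0, rows = 2,
                         per_row = 3, ...) {
  generate_orchard(orchard_spec(n_rows = rows, trees_per_row = per_row,
                                noise_sigma = sigma,
                                outlier_fraction = outliers,
                                seed = seed, ...))
}
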