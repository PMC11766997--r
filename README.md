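# orchardlidar

Tree morphometry for orchards from 3D LiDAR point clouds.

Terrestrial LiDAR scans of a fruit orchard — a sensor carried along the
alleys — yield point clouds from which per-tree geometry can be
measured: tree height, canopy volume, and the spacing between trees and
between rows. These numbers drive spray dosing, irrigation planning,
thinning and machinery settings. `orchardlidar` implements the full
processing chain for row-planted orchards, the agreement statistics used
to validate sensor estimates against manual field measurements, and a
synthetic-orchard generator that makes every stage testable against
known geometry (useful because field scans are rarely shareable).

The package is aimed at agricultural engineers and phenotyping
researchers working with decoded terrestrial scans (ASCII PCD, PLY or
x,y,z CSV — packet decoding is out of scope).

## What it computes

With rows along X, cross-row along Y and Z up (all meters):

* **Preprocessing** — two-phase frame correction (rotation by θ about Z,
  then φ about Y in the clockwise convention), radius outlier removal
  (keep a point iff ≥ k other points lie within radius r), voxel-grid
  downsampling (one centroid per occupied cube), optional statistical
  (mean-kNN-distance) filtering, all backed by a kd-tree index with
  split axes cycling X → Y → Z.
* **Segmentation** — RANSAC ground-plane fit (best 3-point consensus,
  refit by total least squares), ground removal with configurable
  clearance, ROI cropping, and two-stage DBSCAN clustering of the x-y
  projection into rows and individual trees.
* **Per-tree features** —

  * height `H_tree = H_max − H_min` (lowest footprint point or fitted
    plane as the base reference),
  * canopy volume as the axis-aligned bounding box of the crown points,
    with optional substitution of a manually measured cross-row width,
  * the ellipsoid ground-truth comparator
    `CV_m = (π/6)·D1·D2·((Ht1−Hs1)+(Ht2−Hs2))/2`,
  * centroids and planar tree/row spacing.
* **Agreement battery** — for paired sensor (x) vs measured (y) values:
  r², RMSE, MAE, bias, sd of differences, the 95% paired-t CI of the
  mean difference, Lin's concordance correlation coefficient, and the
  paired t-test with two-sided p-value, with the internal identity
  `RMSE² = bias² + ((n−1)/n)·s_d²` asserted on every report.
* **Synthetic scenes** — ground plane + trunk cylinders + ellipsoid
  crown shells with Gaussian range noise and uniform outliers, fully
  labeled, with the generating geometry recorded as ground truth.

## Worked example

```r
library(orchardlidar)

# a 2-row x 6-tree orchard: 1 cm range noise, 1% stray outliers
spec <- orchard_spec(n_rows = 2, trees_per_row = 6, seed = 42)
orch <- generate_orchard(spec)
orch$cloud
#> point_cloud: 66586 points
#>   x: [-2.006, 18.007]  y: [-2.009, 5.406]  z: [-0.041, 3.979] m

# run the chain with the desk-scale preset (filters rescaled to the
# synthetic point density; see the vignette)
res <- run_pipeline(orch$cloud, synthetic_pipeline_config(seed = 42),
                    truth = orch$truth)
#> [input] 66586 points
#> [radius-outlier-removal] removed 565 of 66586 points
#> [voxel-downsample] 64794 points
#> [ground-plane] 14644 inliers at 0.050 m
#> [ground-removal] 49563 points
#> [statistical-filter] removed 1382 of 49563 points
#> [clustering] 12 trees in 2 row(s), 0 noise point(s)

res$spacing
#> spacing_result (row-centroid): 10 tree gap(s), 1 row gap(s)
#>   tree spacing: mean 3.197 m
#>   row spacing:  mean 3.393 m

res$agreement$tree_height
#> Agreement report: tree height (m), n = 12
#>   Mean (sensor / measured): 3.17 / 3.16
#>   Sd   (sensor / measured): 0.26 / 0.25
#>   RMSE 0.01 | MAE 0.01 | bias 0.01
#>   r^2 1.00 | CCC 1.00
#>   t = 8.40 (df 11), two-sided p = 0.0000
#>   95% CI of mean difference: (0.01, 0.02)
```

The planted layout was 3.2 m between trees and 3.4 m between rows; the
pipeline recovers both to within 1 cm here, and the twelve estimated
heights track the generating heights with a 1 cm RMSE (the small
positive bias is the noise-ceiling effect on the maximum z, discussed in
the vignette). `res$metrics` holds the per-tree table (height, bounding
box, canopy volume, centroid); passing `out_dir =` writes the metrics
and spacing as CSV, the agreement battery as JSON and the resolved
configuration as YAML.

Real field scans are handled the same way, entering at
`read_point_cloud()` with the field-scale filter defaults in
`pipeline_config()`, plus `read_ground_truth()` for the manual
measurement CSV (column schema in `?read_ground_truth`).

A command-line front end with `simulate`, `preprocess`, `segment`,
`measure`, `validate` and `run` subcommands lives in
`inst/cli/orchardlidar.R`:

```sh
Rscript inst/cli/orchardlidar.R simulate --out-dir demo --rows 2 --trees 6 --seed 1
Rscript inst/cli/orchardlidar.R run --in demo/cloud.pcd \
    --truth demo/ground_truth.csv --out-dir demo/out \
    --ror-k 4 --ror-radius 0.2 --voxel 0.02
```

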