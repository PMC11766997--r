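Package: orchardlidar
Title: Orchard Tree Morphometry from 3D LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for extracting geometric features of orchard fruit trees
    (tree height, canopy volume, tree spacing and row spacing) from
    three-dimensional LiDAR point clouds. Provides readers and writers for
    ASCII PCD, PLY and XYZ/CSV clouds, coordinate-frame correction,
    radius-outlier removal and voxel-grid downsampling backed by a kd-tree
    spatial index, RANSAC ground-plane segmentation, DBSCAN clustering of
    individual trees and rows, per-tree morphometrics, and a
    method-agreement battery (r-squared, RMSE, MAE, bias, paired-t
    confidence intervals and Lin's concordance correlation) for validating
    sensor estimates against manual field measurements. A synthetic-orchard
    generator with known per-point labels makes the whole pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
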