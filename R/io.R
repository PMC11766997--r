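#' Read a point cloud from PCD, PLY or XYZ/CSV
#'
#' Supported on-disk formats are ASCII PCD (header dialect
#' `VERSION`/`FIELDS`/`SIZE`/`TYPE`/`COUNT`/`WIDTH`/`HEIGHT`/`POINTS`/
#' `DATA ascii`), ASCII PLY, and plain `x,y,z[,intensity]` CSV without a
#' required header. Rows that do not parse to finite coordinates are
#' dropped and their count reported via [message()].
#'
#' @param path file to read.
#' @param format one of `"pcd"`, `"ply"`, `"xyz-csv"`; guessed from the
#'   file extension when `NULL` (`.pcd`, `.ply`, anything else = CSV).
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read point cloud: no such file: ", path)
  format <- format %||% guess_cloud_format(path)
  format <- match.arg(format, c("pcd", "ply", "xyz-csv"))
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(format,
    "pcd" = parse_pcd(lines, path),
    "ply" = parse_ply(lines, path),
    "xyz-csv" = parse_xyz_rows(lines))
  if (parsed$n_rejected > 0L)
    message(sprintf("read_point_cloud: rejected %d non-numeric/non-finite row(s) in %s",
                    parsed$n_rejected, path))
  if (nrow(parsed$points) == 0L)
    stop("empty cloud: no valid points in ", path)
  point_cloud(parsed$points, intensity = parsed$intensity)
}

#' Write a point cloud to PCD, PLY or XYZ/CSV
#'
#' Coordinates are written with 9 decimal digits so a read/write round
#' trip agrees to better than 1e-6 m in every supported format.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param path output file.
#' @param format one of `"pcd"`, `"ply"`, `"xyz-csv"`; guessed from the
#'   extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- n_points(cloud)
  if (n == 0L) stop("refusing to write an empty point cloud")
  format <- format %||% guess_cloud_format(path)
  format <- match.arg(format, c("pcd", "ply", "xyz-csv"))
  has_int <- !is.null(cloud$intensity)
  vals <- cloud$points
  if (has_int) vals <- cbind(vals, cloud$intensity)
  body <- apply(vals, 1L, function(r) paste(sprintf("%.9f", r),
                                            collapse = if (format == "xyz-csv") "," else " "))
  header <- switch(format,
    "pcd" = {
      fields <- if (has_int) "x y z intensity" else "x y z"
      k <- if (has_int) 4L else 3L
      c("# .PCD v0.7 - Point Cloud Data file format",
        "VERSION 0.7",
        paste("FIELDS", fields),
        paste("SIZE", paste(rep("4", k), collapse = " ")),
        paste("TYPE", paste(rep("F", k), collapse = " ")),
        paste("COUNT", paste(rep("1", k), collapse = " ")),
        paste("WIDTH", n),
        "HEIGHT 1",
        "VIEWPOINT 0 0 0 1 0 0 0",
        paste("POINTS", n),
        "DATA ascii")
    },
    "ply" = {
      props <- c("property float x", "property float y", "property float z")
      if (has_int) props <- c(props, "property float intensity")
      c("ply", "format ascii 1.0",
        paste("element vertex", n), props, "end_header")
    },
    "xyz-csv" = character(0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

guess_cloud_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, pcd = "pcd", ply = "ply", "xyz-csv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse numeric coordinate rows given as character lines; returns points,
# optional 4th-column intensity, and the rejected-row count
parse_xyz_rows <- function(lines, sep = ",") {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(list(points = matrix(numeric(0), ncol = 3), intensity = NULL,
                n_rejected = 0L))
  splitter <- if (identical(sep, ",")) "[,;[:space:]]+" else "[[:space:]]+"
  parts <- strsplit(trimws(lines), splitter)
  vals <- suppressWarnings(lapply(parts, as.numeric))
  ok <- vapply(vals, function(v) length(v) >= 3L && all(is.finite(v[1:3])),
               logical(1))
  pts <- do.call(rbind, lapply(vals[ok], function(v) v[1:3]))
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
  inten <- NULL
  if (all(vapply(vals[ok], length, integer(1)) >= 4L) && sum(ok) > 0L) {
    inten4 <- vapply(vals[ok], function(v) v[4], numeric(1))
    if (all(is.finite(inten4))) inten <- inten4
  }
  list(points = pts, intensity = inten, n_rejected = sum(!ok))
}

parse_pcd <- function(lines, path) {
  data_at <- grep("^DATA\\b", lines)
  if (length(data_at) == 0L) stop("not an ASCII PCD file (no DATA line): ", path)
  data_at <- data_at[1]
  if (!grepl("ascii", lines[data_at], ignore.case = TRUE))
    stop("only DATA ascii PCD files are supported: ", path)
  header <- lines[seq_len(data_at)]
  fields_line <- grep("^FIELDS\\b", header, value = TRUE)
  if (length(fields_line) == 0L) stop("PCD header missing FIELDS: ", path)
  fields <- strsplit(trimws(sub("^FIELDS", "", fields_line[1])), "[[:space:]]+")[[1]]
  need <- match(c("x", "y", "z"), fields)
  if (any(is.na(need))) stop("PCD FIELDS must include x, y and z: ", path)
  parsed <- parse_xyz_generic(lines[-seq_len(data_at)], fields, need)
  parsed
}

parse_ply <- function(lines, path) {
  if (length(lines) == 0L || !grepl("^ply", lines[1]))
    stop("not a PLY file: ", path)
  end_at <- grep("^end_header", lines)
  if (length(end_at) == 0L) stop("PLY header not terminated: ", path)
  end_at <- end_at[1]
  header <- lines[seq_len(end_at)]
  if (!any(grepl("format[[:space:]]+ascii", header)))
    stop("only ASCII PLY files are supported: ", path)
  props <- sub("^property[[:space:]]+[[:alnum:]_]+[[:space:]]+", "",
               grep("^property\\b", header, value = TRUE))
  need <- match(c("x", "y", "z"), props)
  if (any(is.na(need))) stop("PLY must declare x, y and z vertex properties: ", path)
  parse_xyz_generic(lines[-seq_len(end_at)], props, need)
}

parse_xyz_generic <- function(body, fields, xyz_cols) {
  parsed <- parse_xyz_rows_generic(body, length(fields))
  pts <- parsed$values[, xyz_cols, drop = FALSE]
  inten <- NULL
  icol <- match("intensity", fields)
  if (!is.na(icol) && nrow(parsed$values) > 0L)
    inten <- parsed$values[, icol]
  keep <- if (nrow(pts) > 0L) apply(pts, 1L, function(r) all(is.finite(r))) else logical(0)
  list(points = pts[keep, , drop = FALSE],
       intensity = if (!is.null(inten)) inten[keep],
       n_rejected = parsed$n_rejected + sum(!keep))
}

parse_xyz_rows_generic <- function(lines, n_fields) {
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  vals <- suppressWarnings(lapply(parts, as.numeric))
  ok <- vapply(vals, function(v) length(v) >= n_fields && !anyNA(v[seq_len(n_fields)]),
               logical(1))
  m <- do.call(rbind, lapply(vals[ok], function(v) v[seq_len(n_fields)]))
  if (is.null(m)) m <- matrix(numeric(0), ncol = n_fields)
  list(values = m, n_rejected = sum(!ok))
}

#' Read manual orchard ground truth from CSV
#'
#' The CSV schema is this package's own (the field protocol it encodes is
#' a measuring-post survey from two perpendicular positions). Required
#' columns: `tree_id`, `row_index`, `position_in_row`, `height_m`,
#' `d1_m`, `d2_m`, `ht1_m`, `hs1_m`, `ht2_m`, `hs2_m`, `tree_spacing_m`,
#' `row_spacing_m`. `d1_m`/`d2_m` are the crown diameters along and
#' across the row; `ht*_m`/`hs*_m` are the canopy top and base reference
#' heights from the two measuring positions; the two spacing columns hold
#' the planted orchard layout and must be constant across rows.
#'
#' @param path CSV file.
#' @return An object of class `orchard_truth`: list with a per-tree data
#'   frame `trees` plus scalars `tree_spacing` and `row_spacing` (m).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("cannot read ground truth: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tree_id", "row_index", "position_in_row", "height_m",
                "d1_m", "d2_m", "ht1_m", "hs1_m", "ht2_m", "hs2_m",
                "tree_spacing_m", "row_spacing_m")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("ground-truth CSV missing column(s): ", paste(missing, collapse = ", "))
  orchard_truth(trees = df[, setdiff(names(df), c("tree_spacing_m", "row_spacing_m")), drop = FALSE],
                tree_spacing = df$tree_spacing_m[1],
                row_spacing = df$row_spacing_m[1])
}

#' Assemble and validate an orchard ground-truth record
#'
#' @param trees per-tree data frame (see [read_ground_truth()] for columns).
#' @param tree_spacing,row_spacing planted spacings in meters.
#' @return An `orchard_truth` object.
#' @export
orchard_truth <- function(trees, tree_spacing, row_spacing) {
  trees <- as.data.frame(trees)
  if (anyDuplicated(trees$tree_id))
    stop("duplicate tree_id in ground truth")
  for (i in seq_len(nrow(trees))) {
    r <- trees[i, ]
    id <- r$tree_id
    if (r$hs1_m < 0 || r$hs2_m < 0 || r$ht1_m < r$hs1_m || r$ht2_m < r$hs2_m)
      stop(sprintf("tree %s: reference heights must satisfy Ht >= Hs >= 0", id))
    if (r$d1_m < 0 || r$d2_m < 0)
      stop(sprintf("tree %s: crown diameters must be non-negative", id))
    if (r$height_m < 0)
      stop(sprintf("tree %s: height must be non-negative", id))
  }
  if (tree_spacing <= 0 || row_spacing <= 0)
    stop("planted spacings must be positive")
  structure(list(trees = trees, tree_spacing = tree_spacing,
                 row_spacing = row_spacing),
            class = "orchard_truth")
}

#' Write orchard ground truth to CSV
#' @param truth an `orchard_truth` object.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "orchard_truth"))
  df <- truth$trees
  df$tree_spacing_m <- truth$tree_spacing
  df$row_spacing_m <- truth$row_spacing
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.orchard_truth <- function(x, ...) {
  cat(sprintf("orchard_truth: %d trees, planted spacing %.2f m (tree) x %.2f m (row)\n",
              nrow(x$trees), x$tree_spacing, x$row_spacing))
  invisible(x)
}
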