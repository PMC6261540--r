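#' The fixed 61x61 pixel grid of the voronoi image
#'
#' One pixel per degree of visual angle over the tested 30-degree radius:
#' image row `i` and column `j` (1-based) map to degrees as `x = j - 31`,
#' `y = 31 - i`, so the grid covers `[-30, 30]` on both axes and the visual
#' field origin (0, 0) sits at image coordinate (31, 31).
#'
#' @return A list with `side` (61), and 61x61 matrices `x` and `y` giving the
#'   degree coordinates of every pixel.
#' @examples
#' g <- pixel_grid()
#' g$x[31, 31]  # 0
#' g$y[31, 31]  # 0
#' @export
pixel_grid <- function() {
  side <- 61L
  j <- matrix(rep(seq_len(side), each = side), side, side)
  i <- matrix(rep(seq_len(side), times = side), side, side)
  list(side = side, x = j - 31, y = 31 - i)
}

#' Nearest-seed region assignment for a test pattern
#'
#' Assigns every pixel of the 61x61 grid to the test location (seed) that
#' minimizes the Euclidean distance in degree space. Pixels equidistant from
#' several seeds go to the lowest seed index, which makes the assignment
#' deterministic and stable under seed order. Blind-spot locations are by
#' default excluded from seeding, so their territory falls to neighbouring
#' seeds; assignment labels always refer to the pattern's original location
#' indices.
#'
#' @param pattern a [test_pattern()].
#' @param include_blind_spot also seed blind-spot locations.
#' @return An object of class `"vf_region_map"` with fields `assignment`
#'   (61x61 integer matrix of location indices), `sizes` (pixel count per
#'   location, length `L`, zero for excluded seeds), `seeds` (indices used)
#'   and `pattern_id`.
#' @export
region_assignment <- function(pattern, include_blind_spot = FALSE) {
  stopifnot(inherits(pattern, "test_pattern"))
  loc <- pattern$locations
  seeds <- if (include_blind_spot) seq_len(pattern$L) else which(!loc$blind_spot)
  if (length(seeds) == 0) stop_fmt("pattern has no usable (non-blind-spot) seeds")
  g <- pixel_grid()
  px <- as.vector(g$x)
  py <- as.vector(g$y)
  d2 <- outer(px, loc$x[seeds], "-")^2 + outer(py, loc$y[seeds], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  assignment <- matrix(seeds[nearest], g$side, g$side)
  sizes <- tabulate(assignment, nbins = pattern$L)
  structure(list(assignment = assignment, sizes = sizes, seeds = seeds,
                 pattern_id = pattern$pattern_id, L = pattern$L),
            class = "vf_region_map")
}

#' @export
print.vf_region_map <- function(x, ...) {
  cat(sprintf("Region map for pattern '%s': %d seeds over %d pixels\n",
              x$pattern_id, length(x$seeds), sum(x$sizes)))
  invisible(x)
}

# Mirrored-pattern region map without recomputation: negating all seed x
# coordinates mirrors the nearest-seed assignment about the vertical axis.
mirror_region_map <- function(region_map) {
  region_map$assignment <- region_map$assignment[, rev(seq_len(ncol(region_map$assignment)))]
  region_map
}

#' Rasterize one examination into a voronoi image
#'
#' Every pixel takes the sensitivity deviation of its assigned seed, giving a
#' piece-wise constant 61x61 image. Left-eye (OS) records are mirrored to OD
#' orientation first (equivalent to mirroring image columns), so all images
#' share a single orientation.
#'
#' @param record a single-row `"vf_table"` data frame.
#' @param region_map a [region_assignment()] result for the record's pattern
#'   in OD orientation.
#' @param pattern the [test_pattern()] (used to check vector length).
#' @param flip_left mirror OS records to OD orientation (default `TRUE`).
#' @return An object of class `"voronoi_image"`: `values` (61x61 dB matrix),
#'   `region_map`, and `source` (subject/eye/group of the record).
#' @export
voronoi_image <- function(record, region_map, pattern, flip_left = TRUE) {
  stopifnot(inherits(region_map, "vf_region_map"))
  record <- as.data.frame(record)
  if (nrow(record) != 1) stop_fmt("voronoi_image expects a single record")
  r <- as.numeric(record[, vf_dev_cols(region_map$L)])
  if (length(r) != region_map$L)
    stop_fmt("deviation vector length %d does not match pattern L = %d",
             length(r), region_map$L)
  rm_use <- if (flip_left && identical(record$eye, "OS"))
    mirror_region_map(region_map) else region_map
  values <- matrix(r[rm_use$assignment], nrow(rm_use$assignment),
                   ncol(rm_use$assignment))
  structure(list(values = values, region_map = rm_use,
                 source = record[, c("subject_id", "eye", "group")]),
            class = "voronoi_image")
}

#' Rasterize a whole VF table into model-ready image columns
#'
#' @inheritParams voronoi_image
#' @param records a `"vf_table"` data frame.
#' @return A 3721 x n matrix, one column per examination, pixels in
#'   column-major image order.
#' @export
voronoi_image_matrix <- function(records, region_map, pattern, flip_left = TRUE) {
  n <- nrow(records)
  L <- region_map$L
  dev <- vf_deviations(records, pattern)
  a_od <- as.vector(region_map$assignment)
  a_os <- as.vector(mirror_region_map(region_map)$assignment)
  out <- matrix(0, length(a_od), n)
  for (i in seq_len(n)) {
    a <- if (flip_left && records$eye[i] == "OS") a_os else a_od
    out[, i] <- dev[i, a]
  }
  out
}

#' @export
print.voronoi_image <- function(x, ...) {
  cat(sprintf("Voronoi image (%dx%d), %d regions, value range [%.2f, %.2f] dB\n",
              nrow(x$values), ncol(x$values), length(x$region_map$seeds),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.voronoi_image <- function(x, main = NULL, ...) {
  plot_field_matrix(x$values, main = main %||% "Voronoi image (dB deviation)",
                    col = grDevices::hcl.colors(64, "Blue-Red 2", rev = TRUE), ...)
}

# Shared raster display: matrix is in image convention (row 1 = top).
plot_field_matrix <- function(m, main = "", col = grDevices::hcl.colors(64), ...) {
  graphics::image(x = seq(-30, 30), y = seq(-30, 30),
                  z = t(m[rev(seq_len(nrow(m))), ]),
                  xlab = "x (degrees)", ylab = "y (degrees)",
                  main = main, col = col, useRaster = TRUE, asp = 1, ...)
  invisible(NULL)
}

#' Export a voronoi image or saliency map as a plain-text matrix
#'
#' Writes 61 rows by 61 tab-separated columns in image orientation.
#'
#' @param x a `"voronoi_image"` or `"vf_saliency"` object, or a bare matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(x, path) {
  m <- if (is.matrix(x)) x else x$values
  utils::write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a voronoi image or saliency map as a PNG heatmap
#'
#' @inheritParams write_matrix_txt
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
write_map_png <- function(x, path, width = 480, height = 480) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  if (inherits(x, "voronoi_image")) plot(x)
  else if (inherits(x, "vf_saliency")) plot(x)
  else plot_field_matrix(x)
  invisible(path)
}
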