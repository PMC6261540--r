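#' Construct a perimetry test pattern
#'
#' A test pattern is the fixed set of retinal locations probed by a perimeter
#' program (e.g. OCTOPUS G1, Humphrey 24-2), given as x/y eccentricities in
#' degrees of visual angle in right-eye (OD) orientation. The location order is
#' the order of the sensitivity-deviation vector of every examination recorded
#' with that pattern. Locations falling on the physiological blind spot are
#' flagged and excluded by default from index computation and voronoi seeding.
#'
#' @param pattern_id short name, e.g. `"24-2"`.
#' @param x,y numeric vectors of location coordinates in degrees, in
#'   `[-30, 30]`.
#' @param blind_spot logical vector flagging blind-spot locations.
#' @return An object of class `"test_pattern"` with fields `pattern_id`,
#'   `locations` (data frame with columns `x`, `y`, `blind_spot`) and `L`.
#' @examples
#' p <- test_pattern("toy", x = c(-10, 0, 10), y = c(0, 5, 0))
#' p$L
#' @export
test_pattern <- function(pattern_id, x, y, blind_spot = rep(FALSE, length(x))) {
  if (!is.character(pattern_id) || length(pattern_id) != 1)
    stop_fmt("pattern_id must be a single string")
  L <- length(x)
  if (L < 1) stop_fmt("a test pattern needs at least one location")
  if (length(y) != L || length(blind_spot) != L)
    stop_fmt("x, y and blind_spot must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_fmt("pattern coordinates must be finite")
  bad <- which(abs(x) > 30 | abs(y) > 30)
  if (length(bad))
    stop_fmt("location %d at (%g, %g) lies outside [-30, 30] degrees",
             bad[1], x[bad[1]], y[bad[1]])
  dup <- which(duplicated(paste(x, y)))
  if (length(dup))
    stop_fmt("duplicate location coordinates at row %d: (%g, %g)",
             dup[1], x[dup[1]], y[dup[1]])
  structure(list(
    pattern_id = pattern_id,
    locations = data.frame(x = as.numeric(x), y = as.numeric(y),
                           blind_spot = as.logical(blind_spot)),
    L = L
  ), class = "test_pattern")
}

#' @export
print.test_pattern <- function(x, ...) {
  cat(sprintf("Test pattern '%s': %d locations (%d blind-spot)\n",
              x$pattern_id, x$L, sum(x$locations$blind_spot)))
  invisible(x)
}

#' Read a test-pattern definition file
#'
#' The pattern CSV dialect has header `index,x_deg,y_deg,blind_spot`, one row
#' per location; the 0-based `index` column defines the order of the deviation
#' vector.
#'
#' @param path path to a pattern CSV file.
#' @param pattern_id pattern name; defaults to the file name without extension.
#' @return A [test_pattern()] object, location order preserved from the file.
#' @seealso [builtin_pattern()] for the charts shipped with the package.
#' @export
load_pattern <- function(path, pattern_id = NULL) {
  if (!file.exists(path)) stop_fmt("pattern file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "x_deg", "y_deg", "blind_spot")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("pattern file %s is missing column(s): %s", path,
             paste(miss, collapse = ", "))
  if (nrow(df) < 1) stop_fmt("pattern file %s has no locations", path)
  if (!isTRUE(all(sort(df$index) == seq_len(nrow(df)) - 1L)))
    stop_fmt("pattern file %s: index column must be 0..L-1", path)
  df <- df[order(df$index), , drop = FALSE]
  if (!is.numeric(df$x_deg) || !is.numeric(df$y_deg))
    stop_fmt("pattern file %s: x_deg/y_deg must be numeric", path)
  bs <- df$blind_spot
  if (is.character(bs)) bs <- toupper(trimws(bs)) %in% c("TRUE", "T", "1")
  bs <- as.logical(bs)
  if (anyNA(bs)) stop_fmt("pattern file %s: blind_spot must be logical/0-1", path)
  if (is.null(pattern_id))
    pattern_id <- sub("^pattern_", "", sub("\\.[^.]*$", "", basename(path)))
  test_pattern(pattern_id, df$x_deg, df$y_deg, bs)
}

#' Test patterns shipped with the package
#'
#' `"24-2"` is the standard Humphrey 24-2 chart in right-eye orientation: 54
#' locations on a 6-degree grid within 24 degrees, extended to 27 degrees
#' nasally, with the two locations at (+15, +-3) flagged as blind spot.
#' `"G1"` is a synthetic 59-location layout emulating the density profile of
#' the OCTOPUS G1 program (central condensation, 30-degree extent); it is not
#' the clinical G1 chart and is intended for simulation and testing.
#'
#' @param id `"24-2"` or `"G1"`.
#' @return A [test_pattern()] object.
#' @export
builtin_pattern <- function(id = c("24-2", "G1")) {
  id <- match.arg(id)
  file <- switch(id, "24-2" = "pattern_24-2.csv", "G1" = "pattern_G1_synthetic.csv")
  path <- system.file("extdata", file, package = "vorofield", mustWork = TRUE)
  load_pattern(path, pattern_id = id)
}

vf_dev_cols <- function(L) paste0("d_", seq_len(L) - 1L)

#' Read a visual-field table
#'
#' One row per examination with header
#' `subject_id,eye,group,pattern_id,d_0,...,d_{L-1}`. Deviation columns hold
#' sensitivity deviations in dB (measured minus age-normal, so loss is
#' negative), ordered as the pattern's locations. Left-eye (OS) rows are kept
#' as measured; mirroring to OD orientation is an explicit step
#' ([flip_to_right_eye()]) applied at rasterization time.
#'
#' @param path path to a VF table CSV file.
#' @param pattern the [test_pattern()] the table was recorded with.
#' @return A data frame of class `"vf_table"`, one row per examination.
#' @export
load_vf_table <- function(path, pattern) {
  stopifnot(inherits(pattern, "test_pattern"))
  if (!file.exists(path)) stop_fmt("VF table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  validate_vf_table(df, pattern, where = path)
}

validate_vf_table <- function(df, pattern, where = "vf_table") {
  L <- pattern$L
  need <- c("subject_id", "eye", "group", "pattern_id", vf_dev_cols(L))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("%s: missing column(s): %s (expected L = %d deviation columns)",
             where, paste(miss, collapse = ", "), L)
  extra_dev <- grep("^d_[0-9]+$", names(df), value = TRUE)
  if (length(extra_dev) != L)
    stop_fmt("%s: found %d deviation columns, pattern '%s' has L = %d",
             where, length(extra_dev), pattern$pattern_id, L)
  bad_eye <- which(!df$eye %in% c("OD", "OS"))
  if (length(bad_eye))
    stop_fmt("%s: row %d has unknown eye code '%s' (expected OD or OS)",
             where, bad_eye[1], df$eye[bad_eye[1]])
  bad_grp <- which(!(is.na(df$group) | df$group %in% c("control", "EG")))
  if (length(bad_grp))
    stop_fmt("%s: row %d has unknown group '%s' (expected control, EG or NA)",
             where, bad_grp[1], df$group[bad_grp[1]])
  dv <- df[, vf_dev_cols(L), drop = FALSE]
  for (cn in names(dv)) {
    if (!is.numeric(dv[[cn]]))
      stop_fmt("%s: non-numeric deviation in column %s", where, cn)
  }
  nonfin <- which(!apply(as.matrix(dv), 1, function(r) all(is.finite(r))))
  if (length(nonfin))
    stop_fmt("%s: row %d has a missing or non-finite deviation", where, nonfin[1])
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("vf_table", "data.frame")
  df
}

#' Write a visual-field table
#'
#' Inverse of [load_vf_table()]; writing then reading reproduces all fields.
#'
#' @param records a `"vf_table"` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vf_table <- function(records, path) {
  df <- as.data.frame(records)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Extract the deviation matrix of a VF table
#'
#' @param records a `"vf_table"` data frame.
#' @param pattern the associated [test_pattern()].
#' @param drop_blind_spot drop blind-spot columns (the default for index
#'   computation).
#' @return numeric matrix, rows = examinations, columns = retained locations.
#' @export
vf_deviations <- function(records, pattern, drop_blind_spot = FALSE) {
  m <- as.matrix(records[, vf_dev_cols(pattern$L), drop = FALSE])
  storage.mode(m) <- "double"
  if (drop_blind_spot && any(pattern$locations$blind_spot))
    m <- m[, !pattern$locations$blind_spot, drop = FALSE]
  m
}

#' Mirror a left-eye record into right-eye orientation
#'
#' OD records are returned unchanged. For OS records the horizontal location
#' coordinates are negated (mirror about the vertical meridian), the eye label
#' becomes OD and deviations are untouched — each value stays attached to its
#' (mirrored) location, so the operation is an involution on coordinates.
#'
#' @param record a single-row `"vf_table"` data frame (one examination).
#' @param pattern the [test_pattern()] the record is aligned to.
#' @return `list(record = <record>, pattern = <pattern view>)` where the
#'   pattern view carries the mirrored coordinates for OS input.
#' @export
flip_to_right_eye <- function(record, pattern) {
  stopifnot(inherits(pattern, "test_pattern"))
  if (nrow(record) != 1) stop_fmt("flip_to_right_eye expects a single record")
  if (!record$eye %in% c("OD", "OS"))
    stop_fmt("unknown eye code '%s'", record$eye)
  if (record$eye == "OD") return(list(record = record, pattern = pattern))
  record$eye <- "OD"
  list(record = record, pattern = mirror_pattern(pattern))
}

#' Mirror a test pattern about the vertical meridian
#'
#' @param pattern a [test_pattern()].
#' @return The pattern with all x coordinates negated.
#' @export
mirror_pattern <- function(pattern) {
  test_pattern(pattern$pattern_id, -pattern$locations$x, pattern$locations$y,
               pattern$locations$blind_spot)
}

#' @export
print.vf_table <- function(x, ...) {
  cat(sprintf("VF table: %d examinations, %d subjects (%s)\n",
              nrow(x), length(unique(x$subject_id)),
              paste(sprintf("%s: %d", names(table(x$group, useNA = "ifany")),
                            table(x$group, useNA = "ifany")), collapse = ", ")))
  invisible(x)
}
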