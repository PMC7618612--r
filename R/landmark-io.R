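#' Landmark set for one AP pelvic radiograph
#'
#' Bundles the annotated point coordinates of one image with the schema that
#' names them. Coordinates follow the image convention: origin at the top
#' left, x increasing rightwards, y increasing downwards, in pixel units.
#' All angle computations convert internally to the mathematical y-up frame.
#'
#' @param points A two-column numeric matrix or data frame of (x, y)
#'   coordinates in file order.
#' @param schema A [landmark_schema()].
#' @param image_id Identifier for the radiograph.
#' @param pixel_spacing Optional mm-per-pixel scale (angles are scale
#'   invariant; carried for completeness).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, schema, image_id = "image", pixel_spacing = 1) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) abort("`points` must have exactly two columns (x, y).")
  storage.mode(pts) <- "double"
  dimnames(pts) <- list(NULL, c("x", "y"))
  assert_finite(pts, "points")
  if (schema_max_index(schema) > nrow(pts)) {
    abort(sprintf("Schema references point %d but only %d points are present.",
                  schema_max_index(schema), nrow(pts)))
  }
  structure(
    list(image_id = as.character(image_id), points = pts, schema = schema,
         pixel_spacing = pixel_spacing),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s: %d points, pixel spacing %g\n",
              x$image_id, nrow(x$points), x$pixel_spacing))
  invisible(x)
}

#' Read an annotated point set from disk
#'
#' Accepts the common plain-text dialects for 2-D landmark files: one `x y`
#' pair per line, whitespace- or comma-delimited, with an optional single
#' integer header line giving the point count, and optional `x,y` column
#' headers in CSV files. No coordinate transformation is applied.
#'
#' @param path Path to the point file.
#' @param schema A [landmark_schema()] naming the points.
#' @param image_id Image identifier; defaults to the file name without
#'   extension.
#' @param pixel_spacing Optional mm-per-pixel scale.
#' @return A [landmark_set()].
#' @export
read_points <- function(path, schema, image_id = NULL, pixel_spacing = 1) {
  if (!file.exists(path)) abort(sprintf("Point file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) abort(sprintf("Point file '%s' is empty.", path))

  parse_line <- function(line) {
    fields <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
    suppressWarnings(as.numeric(fields))
  }

  start <- keep[1]
  first <- parse_line(lines[start])
  body <- keep
  if (length(first) == 1 && !is.na(first) && first == round(first)) {
    # single-integer header giving the point count
    body <- keep[-1]
  } else if (all(is.na(first))) {
    # textual header such as "x,y"
    body <- keep[-1]
  }

  pts <- matrix(NA_real_, nrow = length(body), ncol = 2)
  for (i in seq_along(body)) {
    vals <- parse_line(lines[body[i]])
    if (length(vals) != 2 || anyNA(vals)) {
      abort(sprintf("Malformed coordinate pair on line %d of '%s': \"%s\".",
                    body[i], path, trimws(lines[body[i]])))
    }
    pts[i, ] <- vals
  }

  if (schema_max_index(schema) > nrow(pts)) {
    abort(sprintf(
      "Point file '%s' has %d points but the schema requires at least %d.",
      path, nrow(pts), schema_max_index(schema)))
  }
  if (is.null(image_id)) {
    image_id <- sub("\\.[^.]*$", "", basename(path))
  }
  landmark_set(pts, schema, image_id = image_id, pixel_spacing = pixel_spacing)
}

#' Write an annotated point set to disk
#'
#' Writes one `x y` pair per line with an integer point-count header,
#' round-trippable by [read_points()] to six decimals.
#'
#' @param ls A [landmark_set()].
#' @param path Output path.
#' @param header Write the point-count header line?
#' @return `path`, invisibly.
#' @export
write_points <- function(ls, path, header = TRUE) {
  lines <- sprintf("%.6f %.6f", ls$points[, 1], ls$points[, 2])
  if (header) lines <- c(as.character(nrow(ls$points)), lines)
  writeLines(lines, path)
  invisible(path)
}

# Extract the named landmark coordinates for one side, math (y-up) frame.
# Returns a list of coordinate rows or matrices; NULL entries for missing
# optional roles.
side_landmarks <- function(ls, side) {
  roles <- ls$schema[[side]]
  pts <- ls$points
  get1 <- function(idx) c(x = pts[idx, 1], y = -pts[idx, 2])
  contour <- cbind(x = pts[roles$femoral_head_contour, 1],
                   y = -pts[roles$femoral_head_contour, 2])
  list(
    contour = contour,
    rim = get1(roles$lateral_acetabular_rim),
    sourcil = if (!is.null(roles$sourcil_lateral)) get1(roles$sourcil_lateral),
    obturator = get1(roles$obturator_cranial),
    ischial = get1(roles$ischial_caudal),
    teardrop = get1(roles$teardrop_caudal)
  )
}

#' Quality-control report for a landmark set
#'
#' Flags degenerate geometry that would invalidate automated angle
#' measurement: a femoral head contour whose points are collinear (no circle
#' can be fitted), required landmarks missing from the schema or the four
#' constituent reference-line angles disagreeing beyond a spread threshold
#' (suggesting a mis-annotated image). Always returns a report; it never
#' throws.
#'
#' @param ls A [landmark_set()].
#' @param collinearity_tol Tolerance on the normalised thickness of the
#'   contour point cloud (ratio of the smallest to largest singular value of
#'   the centred contour) below which the contour is declared collinear.
#' @param spread_threshold_deg Maximum allowed spread (max minus min, in
#'   degrees) of the four reference-line component angles.
#' @return An object of class `qc_report`: a list with `image_id`, `flags`
#'   (character vector, subset of `degenerate_circle`,
#'   `collinear_head_points`, `missing_landmark`, `reference_lines_disagree`)
#'   and `worst_reference_spread` in degrees.
#' @export
validate_landmarks <- function(ls, collinearity_tol = 1e-8,
                               spread_threshold_deg = 10) {
  flags <- character(0)
  spread <- NA_real_

  required <- c("lateral_acetabular_rim", "obturator_cranial",
                "ischial_caudal", "teardrop_caudal")
  for (s in c("left", "right")) {
    roles <- ls$schema[[s]]
    if (any(!required %in% names(roles)) ||
        length(roles$femoral_head_contour) < 3) {
      flags <- c(flags, "missing_landmark")
    }
  }

  collinear <- FALSE
  degenerate <- FALSE
  for (s in c("left", "right")) {
    contour <- side_landmarks(ls, s)$contour
    centred <- sweep(contour, 2, colMeans(contour))
    sv <- svd(centred, nu = 0, nv = 0)$d
    if (sv[1] == 0 || sv[2] / sv[1] <= collinearity_tol) {
      collinear <- TRUE
      degenerate <- TRUE
    }
  }
  if (collinear) flags <- c(flags, "collinear_head_points")
  if (degenerate) flags <- c(flags, "degenerate_circle")

  if (!("missing_landmark" %in% flags) && !degenerate) {
    ref <- reference_line(ls)
    spread <- ref$spread_deg
    if (spread > spread_threshold_deg) {
      flags <- c(flags, "reference_lines_disagree")
    }
  }

  structure(
    list(image_id = ls$image_id, flags = unique(flags),
         worst_reference_spread = spread),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s (reference spread %.2f deg)\n", x$image_id,
              if (length(x$flags) == 0) "clean" else paste(x$flags, collapse = ", "),
              x$worst_reference_spread))
  invisible(x)
}

#' @rdname validate_landmarks
#' @export
qc_pass <- function(ls, ...) {
  length(validate_landmarks(ls, ...)$flags) == 0
}
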