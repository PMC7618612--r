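#' Landmark schema for an AP pelvic point set
#'
#' A landmark schema names the anatomical roles of the points in an annotated
#' antero-posterior (AP) pelvic radiograph point set and maps each role to
#' point indices (1-based, in file order). Six roles are required per side:
#' the femoral head contour (an index vector of at least three points), the
#' most lateral bony point of the acetabular rim, the most cranial point of
#' the obturator foramen, the most caudal point of the ischial tuberosity and
#' the most caudal point of the pelvic teardrop; the lateral end of the
#' acetabular sourcil is optional and is used for the Wiberg centre edge
#' angle.
#'
#' @param left,right Named lists with elements `femoral_head_contour`
#'   (integer vector, length >= 3), `lateral_acetabular_rim`,
#'   `obturator_cranial`, `ischial_caudal`, `teardrop_caudal` (single
#'   indices) and optionally `sourcil_lateral`.
#' @return An object of class `landmark_schema`.
#' @seealso [default_pelvis_schema()], [schema_from_json()]
#' @export
landmark_schema <- function(left, right) {
  required <- c("femoral_head_contour", "lateral_acetabular_rim",
                "obturator_cranial", "ischial_caudal", "teardrop_caudal")
  check_side <- function(side, name) {
    missing <- setdiff(required, names(side))
    if (length(missing) > 0) {
      abort(sprintf("Schema side '%s' is missing roles: %s.",
                    name, paste(missing, collapse = ", ")))
    }
    side$femoral_head_contour <- as.integer(side$femoral_head_contour)
    if (length(side$femoral_head_contour) < 3) {
      abort(sprintf("Schema side '%s': femoral_head_contour needs >= 3 points.", name))
    }
    singles <- setdiff(names(side), "femoral_head_contour")
    for (role in singles) {
      side[[role]] <- as.integer(side[[role]])
      if (length(side[[role]]) != 1 || is.na(side[[role]])) {
        abort(sprintf("Schema side '%s': role '%s' must be a single index.", name, role))
      }
    }
    overlap <- intersect(side$femoral_head_contour,
                         unlist(side[singles], use.names = FALSE))
    if (length(overlap) > 0) {
      abort(sprintf("Schema side '%s': contour indices overlap single-point roles (%s).",
                    name, paste(overlap, collapse = ", ")))
    }
    side
  }
  out <- structure(
    list(left = check_side(left, "left"), right = check_side(right, "right")),
    class = "landmark_schema"
  )
  out
}

#' @export
print.landmark_schema <- function(x, ...) {
  cat("<landmark_schema>\n")
  for (s in c("left", "right")) {
    roles <- x[[s]]
    cat(sprintf("  %s: contour[%d pts], roles: %s\n", s,
                length(roles$femoral_head_contour),
                paste(setdiff(names(roles), "femoral_head_contour"), collapse = ", ")))
  }
  invisible(x)
}

# Largest point index referenced by the schema.
schema_max_index <- function(schema) {
  max(unlist(schema[c("left", "right")], use.names = FALSE))
}

#' Default bilateral pelvis schema
#'
#' Builds the schema used by the synthetic landmark generator: for each side,
#' `n_contour` femoral head contour points followed by the acetabular rim,
#' the sourcil end (optional), the cranial obturator point, the caudal
#' ischial point and the caudal teardrop point; left side first.
#'
#' @param n_contour Number of femoral head contour points per side.
#' @param with_sourcil Include a `sourcil_lateral` landmark?
#' @return A [landmark_schema()].
#' @export
default_pelvis_schema <- function(n_contour = 24, with_sourcil = TRUE) {
  per_side <- n_contour + 4L + as.integer(with_sourcil)
  build <- function(offset) {
    idx <- offset + seq_len(n_contour)
    k <- offset + n_contour
    side <- list(
      femoral_head_contour = idx,
      lateral_acetabular_rim = k + 1L
    )
    if (with_sourcil) {
      side$sourcil_lateral <- k + 2L
      k <- k + 1L
    }
    side$obturator_cranial <- k + 2L
    side$ischial_caudal <- k + 3L
    side$teardrop_caudal <- k + 4L
    side
  }
  landmark_schema(left = build(0L), right = build(per_side))
}

#' Read a landmark schema from a JSON document
#'
#' The JSON document must contain `left` and `right` objects mapping role
#' names to 1-based point indices (the femoral head contour may be given as
#' an array or as a `[first, last]` range object `{"from": i, "to": j}`).
#'
#' @param path Path to a JSON file.
#' @return A [landmark_schema()].
#' @export
schema_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expand <- function(side) {
    fh <- side$femoral_head_contour
    if (is.list(fh) && !is.null(fh$from)) {
      side$femoral_head_contour <- seq.int(fh$from, fh$to)
    }
    side
  }
  landmark_schema(left = expand(doc$left), right = expand(doc$right))
}
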