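trivial_schema <- landmark_schema(
  left = list(femoral_head_contour = 1:3, lateral_acetabular_rim = 4,
              obturator_cranial = 5, ischial_caudal = 6, teardrop_caudal = 7),
  right = list(femoral_head_contour = 8:10, lateral_acetabular_rim = 11,
               obturator_cranial = 12, ischial_caudal = 13, teardrop_caudal = 14)
)

test_that("point files round-trip through read and write", {
  ls <- generate_landmarks(pelvis_config(landmark_noise_sd = 0.3, seed = 4))
  path <- withr::local_tempfile(fileext = ".pts")
  write_points(ls, path)
  back <- read_points(path, ls$schema)
  expect_equal(back$points, ls$points, tolerance = 1e-6)

  # without the count header, and comma-delimited
  writeLines(sprintf("%.6f,%.6f", ls$points[, 1], ls$points[, 2]), path)
  back2 <- read_points(path, ls$schema)
  expect_equal(back2$points, ls$points, tolerance = 1e-6)
})

test_that("a minimal three-point file parses in file order", {
  path <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("0 0", "1 0", "0 1"), path)
  sch <- list(left = list(femoral_head_contour = 1:3))
  # bypass full schema validation: only indices are checked at read time
  class(sch) <- "landmark_schema"
  ls <- read_points(path, sch)
  expect_equal(nrow(ls$points), 3)
  expect_equal(ls$points[2, ], c(x = 1, y = 0))
})

test_that("malformed coordinate lines raise an error naming the line", {
  path <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("0 0", "a b", "0 1"), path)
  sch <- structure(list(left = list(femoral_head_contour = 1:3)),
                   class = "landmark_schema")
  expect_error(read_points(path, sch), "line 2")
})

test_that("too few points for the schema is a schema error", {
  path <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("0 0", "1 0", "0 1"), path)
  expect_error(read_points(path, trivial_schema), "schema requires")
})

test_that("schema construction enforces roles, ranges and disjointness", {
  expect_error(landmark_schema(left = list(femoral_head_contour = 1:3),
                               right = list()), "missing roles")
  expect_error(
    landmark_schema(
      left = list(femoral_head_contour = 1:2, lateral_acetabular_rim = 3,
                  obturator_cranial = 4, ischial_caudal = 5, teardrop_caudal = 6),
      right = trivial_schema$right),
    ">= 3 points")
  expect_error(
    landmark_schema(
      left = list(femoral_head_contour = 1:3, lateral_acetabular_rim = 3,
                  obturator_cranial = 4, ischial_caudal = 5, teardrop_caudal = 6),
      right = trivial_schema$right),
    "overlap")
})

test_that("schema round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(left = list(femoral_head_contour = list(from = 1, to = 3),
                     lateral_acetabular_rim = 4, obturator_cranial = 5,
                     ischial_caudal = 6, teardrop_caudal = 7),
         right = list(femoral_head_contour = 8:10, lateral_acetabular_rim = 11,
                      obturator_cranial = 12, ischial_caudal = 13,
                      teardrop_caudal = 14)),
    path, auto_unbox = TRUE)
  sch <- schema_from_json(path)
  expect_s3_class(sch, "landmark_schema")
  expect_equal(sch$left$femoral_head_contour, 1:3)
  expect_equal(sch$right$teardrop_caudal, 14L)
})

test_that("an ideal synthetic pelvis passes QC with no flags", {
  ls <- generate_landmarks(pelvis_config())
  qc <- validate_landmarks(ls)
  expect_length(qc$flags, 0)
  expect_equal(qc$worst_reference_spread, 0, tolerance = 1e-8)
  # purity: identical input, identical report
  expect_identical(qc, validate_landmarks(ls))
})

test_that("collinear head contours are flagged as degenerate", {
  ls <- generate_landmarks(pelvis_config(n_head_contour_points = 3))
  pts <- ls$points
  idx <- ls$schema$left$femoral_head_contour
  pts[idx, ] <- cbind(c(0, 1, 2), c(0, 1, 2))  # exactly collinear
  bad <- landmark_set(pts, ls$schema, image_id = "collinear")
  qc <- validate_landmarks(bad)
  expect_true("collinear_head_points" %in% qc$flags)
  expect_true("degenerate_circle" %in% qc$flags)
})

test_that("disagreeing reference lines are flagged with their spread", {
  ls <- generate_landmarks(pelvis_config())
  pts <- ls$points
  # rotate the teardrop pair about its midpoint by 30 degrees
  i_l <- ls$schema$left$teardrop_caudal
  i_r <- ls$schema$right$teardrop_caudal
  mid <- colMeans(pts[c(i_l, i_r), ])
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts[c(i_l, i_r), ] <- sweep(sweep(pts[c(i_l, i_r), ], 2, mid) %*% t(rot), 2, mid, "+")
  bad <- landmark_set(pts, ls$schema, image_id = "tilted")
  qc <- validate_landmarks(bad, spread_threshold_deg = 10)
  expect_true("reference_lines_disagree" %in% qc$flags)
  expect_equal(qc$worst_reference_spread, 30, tolerance = 1e-6)
  # below threshold, the same geometry passes
  expect_false("reference_lines_disagree" %in%
                 validate_landmarks(bad, spread_threshold_deg = 45)$flags)
})
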