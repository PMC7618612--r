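test_that("exact circles are recovered exactly", {
  pts <- cbind(c(1, 0, -1, 0), c(0, 1, 0, -1))
  for (method in c("algebraic", "geometric")) {
    fit <- fit_circle(pts, method = method)
    expect_equal(fit$center, c(0, 0), tolerance = 1e-10)
    expect_equal(fit$radius, 1, tolerance = 1e-10)
    expect_equal(fit$rms_residual, 0, tolerance = 1e-10)
  }
})

test_that("three non-collinear points give their circumcircle (zero residual)", {
  set.seed(11)
  for (rep in 1:20) {
    pts <- matrix(rnorm(6), 3, 2)
    if (abs(det(cbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ]))) < 1e-3) next
    fit <- fit_circle(pts)
    expect_lt(fit$rms_residual, 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_circle(cbind(0:1, 0:1)), "at least 3")
  expect_error(fit_circle(cbind(0:4, 0:4)), "collinear")
})

test_that("geometric refinement matches a brute-force minimiser of the radial loss", {
  set.seed(21)
  for (rep in 1:20) {
    centre <- runif(2, -5, 5)
    r <- runif(1, 2, 8)
    th <- runif(20, 0, 2 * pi)
    pts <- cbind(centre[1] + (r + rnorm(20, 0, 0.05)) * cos(th),
                 centre[2] + (r + rnorm(20, 0, 0.05)) * sin(th))
    ours <- fit_circle(pts, method = "geometric")
    bf <- brute_force_circle(pts)
    expect_equal(ours$center, bf$center, tolerance = 1e-6)
    expect_equal(ours$radius, bf$radius, tolerance = 1e-6)
    # and the noisy fit stays close to the generating truth
    expect_lt(max(abs(ours$center - centre)), 0.05)
    expect_lt(abs(ours$radius - r), 0.05)
  }
})

test_that("geometric loss never exceeds the algebraic loss", {
  set.seed(31)
  for (rep in 1:20) {
    th <- runif(15, 0, 2 * pi)
    pts <- cbind(3 + (2 + rnorm(15, 0, 0.3)) * cos(th),
                 -1 + (2 + rnorm(15, 0, 0.3)) * sin(th))
    alg <- fit_circle(pts, "algebraic")
    geo <- fit_circle(pts, "geometric")
    loss <- function(f) pincer:::circle_loss(pts, f$center, f$radius)
    expect_lte(loss(geo), loss(alg) + 1e-12)
  }
})

test_that("the reference line averages the four component angles", {
  ls <- generate_landmarks(pelvis_config())
  ref <- reference_line(ls)
  expect_equal(ref$angle_deg, 0, tolerance = 1e-9)
  expect_equal(ref$spread_deg, 0, tolerance = 1e-9)

  rot <- reference_line(generate_landmarks(pelvis_config(pelvis_rotation_deg = 5)))
  expect_equal(rot$angle_deg, 5, tolerance = 1e-9)
  expect_equal(mean(rot$component_angles_deg), rot$angle_deg)

  # constructed component angles 1,2,3,4 must average to 2.5
  ls2 <- generate_landmarks(pelvis_config())
  pts <- ls2$points
  # tilt each landmark pair individually to angles 1..4 (math frame)
  sch <- ls2$schema
  roles <- c("obturator_cranial", "ischial_caudal", "teardrop_caudal")
  angles <- c(2, 3, 4)  # head-centre line stays at its constructed angle
  pts2 <- ls2$points
  rotate_pair <- function(pts, i_l, i_r, deg) {
    mid <- colMeans(pts[c(i_l, i_r), ])
    th <- -deg * pi / 180  # image y-down: negative math rotation
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    pts[c(i_l, i_r), ] <- sweep(sweep(pts[c(i_l, i_r), ], 2, mid) %*% t(R), 2, mid, "+")
    pts
  }
  # head centres: rotate every left/right contour point set about the global midpoint
  all_contour <- c(sch$left$femoral_head_contour, sch$right$femoral_head_contour)
  mid <- colMeans(pts2[all_contour, ])
  th <- -1 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pts2[all_contour, ] <- sweep(sweep(pts2[all_contour, ], 2, mid) %*% t(R), 2, mid, "+")
  for (j in seq_along(roles)) {
    pts2 <- rotate_pair(pts2, sch$left[[roles[j]]], sch$right[[roles[j]]], angles[j])
  }
  ref2 <- reference_line(landmark_set(pts2, sch))
  expect_equal(unname(ref2$component_angles_deg), c(1, 2, 3, 4), tolerance = 1e-9)
  expect_equal(ref2$angle_deg, 2.5, tolerance = 1e-9)
})

test_that("constructed LCEA and Wiberg angles are measured exactly", {
  ls <- generate_landmarks(pelvis_config(true_lcea_left = 40, true_lcea_right = 43,
                                         wcea_offset = -5))
  expect_equal(lcea(ls, "left")$lcea_deg, 40, tolerance = 1e-9)
  expect_equal(lcea(ls, "right")$lcea_deg, 43, tolerance = 1e-9)
  m <- wiberg_cea(ls, "left")
  expect_equal(m$wcea_deg, 35, tolerance = 1e-9)
  expect_lt(m$wcea_deg, m$lcea_deg)  # sourcil medial to rim by construction

  # rim exactly on the cranial vertical
  ls0 <- generate_landmarks(pelvis_config(true_lcea_left = 0))
  expect_equal(lcea(ls0, "left")$lcea_deg, 0, tolerance = 1e-9)
})

test_that("tilt correction cancels rigid rotation of the whole pelvis", {
  for (rho in seq(-10, 10, by = 2.5)) {
    ls <- generate_landmarks(pelvis_config(true_lcea_left = 43, true_lcea_right = 43,
                                           pelvis_rotation_deg = rho))
    expect_equal(lcea(ls, "left")$lcea_deg, 43, tolerance = 1e-6)
    expect_equal(lcea(ls, "right")$lcea_deg, 43, tolerance = 1e-6)
  }
})

test_that("angles are invariant under translation and uniform scaling, and side-symmetric", {
  ls <- generate_landmarks(pelvis_config(true_lcea_left = 38, true_lcea_right = 29,
                                         pelvis_rotation_deg = 3))
  base_l <- lcea(ls, "left")$lcea_deg
  base_r <- lcea(ls, "right")$lcea_deg
  moved <- landmark_set(ls$points * 2.5 + 100, ls$schema)
  expect_equal(lcea(moved, "left")$lcea_deg, base_l, tolerance = 1e-9)
  expect_equal(lcea(moved, "right")$lcea_deg, base_r, tolerance = 1e-9)

  # mirror the image about a vertical axis: left and right hips swap roles
  mirrored_pts <- ls$points
  mirrored_pts[, 1] <- -mirrored_pts[, 1]
  swapped_schema <- landmark_schema(left = ls$schema$right, right = ls$schema$left)
  mirrored <- landmark_set(mirrored_pts, swapped_schema)
  expect_equal(lcea(mirrored, "right")$lcea_deg, base_l, tolerance = 1e-9)
  expect_equal(lcea(mirrored, "left")$lcea_deg, base_r, tolerance = 1e-9)
})

test_that("without a sourcil landmark the Wiberg angle falls back to the rim", {
  ls <- generate_landmarks(pelvis_config(with_sourcil = FALSE, true_lcea_left = 33))
  m <- wiberg_cea(ls, "left")
  expect_equal(m$wcea_deg, m$lcea_deg)
  expect_true("sourcil_fallback" %in% m$flags)
})

test_that("batch measurement returns one tidy row per hip", {
  sets <- list(generate_landmarks(pelvis_config(true_lcea_left = 41), image_id = "a"),
               generate_landmarks(pelvis_config(n_head_contour_points = 3), image_id = "b"))
  # make image b unmeasurable
  pts <- sets[[2]]$points
  idx <- sets[[2]]$schema$left$femoral_head_contour
  pts[idx, ] <- cbind(c(0, 1, 2), c(0, 1, 2))
  sets[[2]] <- landmark_set(pts, sets[[2]]$schema, image_id = "b")

  tab <- measure_hips(sets)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$lcea_deg[tab$image_id == "a" & tab$side == "left"], 41,
               tolerance = 1e-9)
  expect_true(all(is.na(tab$lcea_deg[tab$image_id == "b"])))
  expect_false(any(tab$qc_pass[tab$image_id == "b"]))
})
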