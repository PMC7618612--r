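#' Configuration for the synthetic pelvis landmark generator
#'
#' Describes a parametric bilateral pelvis whose measurement ground truth
#' is known exactly: femoral head contours on exact circles, rim and
#' sourcil landmarks placed at configured true centre edge angles, and the
#' four horizontal-reference landmark pairs placed symmetrically so that
#' the unrotated pelvis has a zero-degree reference line. Units are
#' pixels, matching typical radiograph annotations.
#'
#' @param head_radius Femoral head radius in pixels.
#' @param head_separation Distance between the two head centres in pixels.
#' @param true_lcea_left,true_lcea_right True lateral centre edge angles
#'   in degrees.
#' @param wcea_offset Degrees added to the LCEA to place the sourcil
#'   landmark (negative = sourcil medial to the rim, the usual anatomy).
#' @param pelvis_rotation_deg Rigid rotation applied to the whole landmark
#'   set (simulates pelvic tilt in the image).
#' @param landmark_noise_sd Isotropic Gaussian noise SD added to every
#'   landmark, in pixels.
#' @param n_head_contour_points Contour points per femoral head.
#' @param with_sourcil Include sourcil landmarks?
#' @param seed RNG seed used by [generate_landmarks()] when noise is drawn.
#' @return A list of class `pelvis_config`.
#' @export
pelvis_config <- function(head_radius = 60, head_separation = 300,
                          true_lcea_left = 36, true_lcea_right = 36,
                          wcea_offset = -3, pelvis_rotation_deg = 0,
                          landmark_noise_sd = 0, n_head_contour_points = 24,
                          with_sourcil = TRUE, seed = NULL) {
  if (head_radius <= 0) abort("head_radius must be positive.")
  if (n_head_contour_points < 3) abort("Need at least 3 head contour points.")
  structure(
    list(head_radius = head_radius, head_separation = head_separation,
         true_lcea_left = true_lcea_left, true_lcea_right = true_lcea_right,
         wcea_offset = wcea_offset, pelvis_rotation_deg = pelvis_rotation_deg,
         landmark_noise_sd = landmark_noise_sd,
         n_head_contour_points = n_head_contour_points,
         with_sourcil = with_sourcil, seed = seed),
    class = "pelvis_config"
  )
}

#' Generate a synthetic annotated pelvis
#'
#' Builds the landmark set described by a [pelvis_config()]: both femoral
#' head contours, rim/sourcil landmarks at the configured true angles, and
#' symmetric obturator, ischial and teardrop reference landmarks. The
#' whole set is rotated rigidly by `pelvis_rotation_deg` (so the measured
#' angles must be invariant to it), Gaussian noise is added and the points
#' are emitted in the image convention (y down). The ground truth is
#' attached as attribute `"truth"`.
#'
#' The hip placed at +x is labelled `left` (an AP radiograph mirrors the
#' patient), so its lateral direction is +x; the right hip mirrors it.
#'
#' @param cfg A [pelvis_config()].
#' @param image_id Identifier for the generated set.
#' @return A [landmark_set()] with attribute `truth` (list of the true
#'   angles and geometry).
#' @export
generate_landmarks <- function(cfg = pelvis_config(), image_id = "synthetic") {
  stopifnot(inherits(cfg, "pelvis_config"))
  n <- cfg$n_head_contour_points
  R <- cfg$head_radius
  half <- cfg$head_separation / 2

  # pelvis frame: y up, origin midway between the head centres
  build_side <- function(side) {
    s <- if (side == "left") 1 else -1
    centre <- c(s * half, 0)
    ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    contour <- cbind(centre[1] + R * cos(ang), centre[2] + R * sin(ang))
    true_lcea <- if (side == "left") cfg$true_lcea_left else cfg$true_lcea_right
    place_ray <- function(theta_deg, dist) {
      th <- theta_deg * pi / 180
      c(centre[1] + dist * s * sin(th), centre[2] + dist * cos(th))
    }
    rim <- place_ray(true_lcea, 1.3 * R)
    sourcil <- if (cfg$with_sourcil) place_ray(true_lcea + cfg$wcea_offset, 1.25 * R)
    obturator <- c(s * 0.35 * cfg$head_separation, -0.45 * cfg$head_separation)
    ischial <- c(s * 0.40 * cfg$head_separation, -0.85 * cfg$head_separation)
    teardrop <- c(s * 0.22 * cfg$head_separation, -0.35 * cfg$head_separation)
    rows <- rbind(contour, rim)
    if (cfg$with_sourcil) rows <- rbind(rows, sourcil)
    rbind(rows, obturator, ischial, teardrop)
  }
  pts <- rbind(build_side("left"), build_side("right"))

  rho <- cfg$pelvis_rotation_deg * pi / 180
  rot <- matrix(c(cos(rho), sin(rho), -sin(rho), cos(rho)), 2)
  pts <- pts %*% t(rot)

  pts <- with_local_seed(cfg$seed, {
    if (cfg$landmark_noise_sd > 0) {
      pts + matrix(rnorm(length(pts), sd = cfg$landmark_noise_sd), ncol = 2)
    } else {
      pts
    }
  })

  # image convention: shift into positive quadrant, flip y
  pts_img <- cbind(pts[, 1] + cfg$head_separation,
                   2 * cfg$head_separation - pts[, 2])
  schema <- default_pelvis_schema(n_contour = n, with_sourcil = cfg$with_sourcil)
  ls <- landmark_set(pts_img, schema, image_id = image_id)
  attr(ls, "truth") <- list(
    true_lcea_left = cfg$true_lcea_left,
    true_lcea_right = cfg$true_lcea_right,
    true_wcea_left = cfg$true_lcea_left + cfg$wcea_offset,
    true_wcea_right = cfg$true_lcea_right + cfg$wcea_offset,
    pelvis_rotation_deg = cfg$pelvis_rotation_deg,
    head_radius = R, head_separation = cfg$head_separation
  )
  ls
}
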