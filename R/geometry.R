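#' Best-fit circle through 2-D points
#'
#' Fits a circle to the femoral head contour. The algebraic method is the
#' Kasa least-squares fit (linear in the circle parameters); the geometric
#' method refines it by Gauss-Newton minimisation of the sum of squared
#' radial residuals \eqn{\sum_i (\lVert p_i - c \rVert - r)^2}, converging
#' when the parameter step falls below `tol` or after `max_iter` iterations.
#'
#' @param points Two-column matrix of (x, y) coordinates; at least three
#'   non-collinear points.
#' @param method `"geometric"` (default: Kasa start plus Gauss-Newton
#'   refinement) or `"algebraic"` (Kasa only).
#' @param tol Convergence tolerance on the Gauss-Newton parameter step.
#' @param max_iter Maximum Gauss-Newton iterations.
#' @return An object of class `circle_fit`: list with `center` (x, y),
#'   `radius`, `rms_residual`, `method`, `converged` and `iterations`.
#' @export
fit_circle <- function(points, method = c("geometric", "algebraic"),
                       tol = 1e-10, max_iter = 100) {
  method <- match.arg(method)
  pts <- as.matrix(points)
  if (nrow(pts) < 3) abort("Circle fit needs at least 3 points.")
  assert_finite(pts, "points")

  x <- pts[, 1]; y <- pts[, 2]
  # collinearity check via the thickness of the centred cloud
  centred <- cbind(x - mean(x), y - mean(y))
  sv <- svd(centred, nu = 0, nv = 0)$d
  if (sv[1] == 0 || sv[2] / sv[1] < 1e-12) {
    abort("Circle fit is degenerate: points are collinear.")
  }

  # Kasa: minimise || x^2 + y^2 - 2ax - 2by - c ||^2, linear least squares
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))
  iterations <- 0L
  converged <- TRUE

  if (method == "geometric") {
    par <- c(center, radius)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dx <- x - par[1]; dy <- y - par[2]
      d <- sqrt(dx^2 + dy^2)
      d[d == 0] <- .Machine$double.eps
      r <- d - par[3]
      J <- cbind(-dx / d, -dy / d, -1)
      step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 3))
      par <- par + step
      iterations <- it
      if (sqrt(sum(step^2)) < tol) {
        converged <- TRUE
        break
      }
    }
    center <- par[1:2]
    radius <- par[3]
  }

  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean((d - radius)^2)),
         method = method, converged = converged, iterations = iterations),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.4f, %.4f), radius %.4f, rms %.2e [%s]\n",
              x$center[1], x$center[2], x$radius, x$rms_residual, x$method))
  invisible(x)
}

# Sum of squared radial residuals of a circle fit on points (math frame).
circle_loss <- function(points, center, radius) {
  d <- sqrt((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
  sum((d - radius)^2)
}

#' Pelvic-tilt horizontal reference line
#'
#' Constructs the horizontal reference used to correct angle measurements
#' for pelvic rotation in the image. Four lines connect the left and right
#' instances of (1) the femoral head centres (from per-side circle fits),
#' (2) the most cranial obturator foramen points, (3) the most caudal
#' ischial tuberosity points and (4) the most caudal teardrop points. Each
#' component angle is normalised to (-90, 90] degrees and the reference
#' angle is their arithmetic mean.
#'
#' @param ls A [landmark_set()].
#' @return An object of class `reference_line`: list with `angle_deg`,
#'   `component_angles_deg` (length 4, named) and `spread_deg`.
#' @export
reference_line <- function(ls) {
  lm_l <- side_landmarks(ls, "left")
  lm_r <- side_landmarks(ls, "right")
  head_l <- fit_circle(lm_l$contour)$center
  head_r <- fit_circle(lm_r$contour)$center

  line_angle <- function(p, q) {
    normalize_angle(atan2(q[2] - p[2], q[1] - p[1]) * 180 / pi)
  }
  comp <- c(
    head_centres = line_angle(head_l, head_r),
    obturator = line_angle(lm_l$obturator, lm_r$obturator),
    ischial = line_angle(lm_l$ischial, lm_r$ischial),
    teardrop = line_angle(lm_l$teardrop, lm_r$teardrop)
  )
  structure(
    list(angle_deg = mean(comp), component_angles_deg = comp,
         spread_deg = max(comp) - min(comp)),
    class = "reference_line"
  )
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<reference_line> %.3f deg (spread %.3f deg)\n",
              x$angle_deg, x$spread_deg))
  invisible(x)
}

# Shared centre edge angle construction: signed angle at the femoral head
# centre between the cranial vertical (perpendicular to the tilt-corrected
# horizontal) and the ray to `target` (math frame coordinates), positive
# when the target lies lateral to the vertical. Lateral is +x for the left
# hip; right hips are mirrored.
centre_edge_angle <- function(center, target, ref_angle_deg, side) {
  v <- target - center
  phi <- ref_angle_deg * pi / 180
  # rotate into the tilt-corrected frame
  rot <- c(cos(phi) * v[1] + sin(phi) * v[2],
           -sin(phi) * v[1] + cos(phi) * v[2])
  s <- if (side == "left") 1 else -1
  as.numeric(atan2(s * rot[1], rot[2]) * 180 / pi)
}

#' Lateral centre edge angle of one hip
#'
#' Measures the LCEA from an annotated AP pelvic point set following the
#' standard automated construction: a best-fit circle locates the femoral
#' head centre; the first leg of the angle is the line through the centre
#' perpendicular to the pelvic-tilt [reference_line()] (pointing cranially);
#' the second leg is the ray from the centre to the most lateral bony point
#' of the acetabulum. The angle is signed: positive when the rim lies
#' lateral to the vertical (more coverage), and is invariant under rigid
#' rotation, translation and uniform scaling of the point set.
#'
#' @param ls A [landmark_set()].
#' @param side `"left"` or `"right"`.
#' @param rim_mode `"landmark"` (default) takes the schema's designated rim
#'   point; `"extremal"` selects the femoral-head-side acetabular point
#'   most lateral in the tilt-corrected frame (here: the more lateral of
#'   rim and sourcil landmarks).
#' @return An object of class `angle_measurement`: list with `side`,
#'   `lcea_deg`, `wcea_deg` (`NA` here; see [wiberg_cea()]), `circle`
#'   ([fit_circle()] result), `reference` ([reference_line()] result) and
#'   `flags`.
#' @export
lcea <- function(ls, side = c("left", "right"), rim_mode = c("landmark", "extremal")) {
  side <- match.arg(side)
  rim_mode <- match.arg(rim_mode)
  lm <- side_landmarks(ls, side)
  ref <- reference_line(ls)
  circ <- fit_circle(lm$contour)

  target <- lm$rim
  flags <- character(0)
  if (rim_mode == "extremal" && !is.null(lm$sourcil)) {
    cand <- rbind(lm$rim, lm$sourcil)
    ang <- apply(cand, 1, function(p) {
      centre_edge_angle(circ$center, p, ref$angle_deg, side)
    })
    target <- cand[which.max(ang), ]
  }

  structure(
    list(side = side,
         lcea_deg = centre_edge_angle(circ$center, target, ref$angle_deg, side),
         wcea_deg = NA_real_,
         circle = circ, reference = ref, flags = flags),
    class = "angle_measurement"
  )
}

#' Wiberg centre edge angle of one hip
#'
#' Identical construction to [lcea()] but the second leg targets the
#' lateral end of the acetabular sourcil, the landmark conventionally used
#' for the Wiberg angle and for the dysplasia criterion (Wiberg CEA <= 25
#' degrees). If the schema carries no sourcil landmark the measurement
#' falls back to the acetabular rim point and records a
#' `"sourcil_fallback"` flag, making the Wiberg angle equal the LCEA.
#'
#' @inheritParams lcea
#' @return An `angle_measurement` with `wcea_deg` set.
#' @export
wiberg_cea <- function(ls, side = c("left", "right")) {
  side <- match.arg(side)
  lm <- side_landmarks(ls, side)
  ref <- reference_line(ls)
  circ <- fit_circle(lm$contour)

  flags <- character(0)
  target <- lm$sourcil
  if (is.null(target)) {
    target <- lm$rim
    flags <- "sourcil_fallback"
  }
  structure(
    list(side = side,
         lcea_deg = centre_edge_angle(circ$center, lm$rim, ref$angle_deg, side),
         wcea_deg = centre_edge_angle(circ$center, target, ref$angle_deg, side),
         circle = circ, reference = ref, flags = flags),
    class = "angle_measurement"
  )
}

#' @export
print.angle_measurement <- function(x, ...) {
  cat(sprintf("<angle_measurement> %s hip: LCEA %.2f deg%s\n", x$side, x$lcea_deg,
              if (is.na(x$wcea_deg)) "" else sprintf(", Wiberg CEA %.2f deg", x$wcea_deg)))
  invisible(x)
}

#' Batch angle measurement over landmark sets
#'
#' Runs QC, the LCEA and the Wiberg CEA for both hips of each landmark set
#' and returns one row per hip, the tabular interface consumed by
#' [classify_morphology()] and the cohort pipeline.
#'
#' @param landmark_sets A list of [landmark_set()] objects (a single set is
#'   accepted).
#' @param collinearity_tol,spread_threshold_deg QC thresholds, see
#'   [validate_landmarks()].
#' @return A tibble with columns `image_id`, `side`, `lcea_deg`, `wcea_deg`,
#'   `rms_residual`, `qc_pass`, `qc_flags`.
#' @export
measure_hips <- function(landmark_sets, collinearity_tol = 1e-8,
                         spread_threshold_deg = 10) {
  if (inherits(landmark_sets, "landmark_set")) landmark_sets <- list(landmark_sets)
  purrr::map_dfr(landmark_sets, function(ls) {
    qc <- validate_landmarks(ls, collinearity_tol, spread_threshold_deg)
    ok <- length(qc$flags) == 0
    purrr::map_dfr(c("left", "right"), function(side) {
      if (ok) {
        m <- wiberg_cea(ls, side)
        tibble(image_id = ls$image_id, side = side,
               lcea_deg = m$lcea_deg, wcea_deg = m$wcea_deg,
               rms_residual = m$circle$rms_residual,
               qc_pass = TRUE,
               qc_flags = paste(m$flags, collapse = ";"))
      } else {
        tibble(image_id = ls$image_id, side = side,
               lcea_deg = NA_real_, wcea_deg = NA_real_,
               rms_residual = NA_real_, qc_pass = FALSE,
               qc_flags = paste(qc$flags, collapse = ";"))
      }
    })
  })
}
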