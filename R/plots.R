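#' Plot a landmark set
#'
#' Shows the annotated points in image orientation (y axis reversed) with
#' the fitted femoral head circles and the tilt reference line, the usual
#' visual check of an automated centre-edge-angle measurement.
#'
#' @param object A [landmark_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot landmark_set
#' @export
autoplot.landmark_set <- function(object, ...) {
  pts <- as_tibble(object$points)
  circles <- purrr::map_dfr(c("left", "right"), function(s) {
    fit <- fit_circle(side_landmarks(object, s)$contour)
    th <- seq(0, 2 * pi, length.out = 120)
    tibble(side = s,
           x = fit$center[1] + fit$radius * cos(th),
           y = -(fit$center[2] + fit$radius * sin(th)))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(group = .data$side),
                       colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$image_id, x = "x (px)", y = "y (px, image)") +
    ggplot2::theme_minimal()
}

#' Plot an inclusion-cascade flow report
#'
#' Bar chart of hips remaining after each filter of the inclusion
#' cascade, annotated with the number removed at each step.
#'
#' @param object A `flow_report` from [apply_filters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flow_report
#' @export
autoplot.flow_report <- function(object, ...) {
  d <- as_tibble(object)
  d$filter <- factor(d$filter, levels = rev(d$filter))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_after, y = .data$filter)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("-", .data$n_removed)),
                       hjust = -0.15, size = 3) +
    ggplot2::labs(x = "hips remaining", y = NULL,
                  title = "Inclusion cascade") +
    ggplot2::theme_minimal()
}

#' Forest plot of stratified risk estimates
#'
#' @param data A tibble of risk estimates with columns `estimate`,
#'   `conf.low`, `conf.high` and a label column (e.g. output of
#'   [relative_risk()] on a stratified table).
#' @param label_col Column naming each stratum.
#' @return A ggplot object.
#' @export
plot_risk_forest <- function(data, label_col = "stratum") {
  d <- as_tibble(data)
  d$label <- factor(d[[label_col]], levels = rev(unique(d[[label_col]])))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(d$kind)[1] %||% "estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Effect plot of a continuation-ratio fit
#'
#' Marginal probabilities of the three RHOA levels at the reference
#' profile (female, mean baseline age and BMI, random effects at zero)
#' for pincer and pincer-free hips, with delta-method intervals.
#'
#' @param object A `hip_cr_fit` from [fit_continuation_ratio()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hip_cr_fit
#' @export
autoplot.hip_cr_fit <- function(object, ...) {
  m <- object$marginal_probabilities
  if (is.null(m)) abort("Fit carries no marginal probabilities (collapsed model).")
  m$level <- factor(m$level, levels = 0:2,
                    labels = c("free of RHOA", "doubtful RHOA", "definite RHOA"))
  m$group <- ifelse(m$pincer == 1, "pincer", "no pincer")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$level, y = .data$probability,
                                  colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "marginal probability", colour = NULL) +
    ggplot2::theme_minimal()
}
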