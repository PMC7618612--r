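#' Tidy a fitted multilevel logistic model
#'
#' One row per fixed-effect term with the coefficient, Wald statistics and
#' odds-ratio scale confidence interval.
#'
#' @param x A `hip_glmm` from [fit_binary_glmm()].
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `odds.ratio`, `conf.low`, `conf.high` (the
#'   last two on the odds-ratio scale).
#' @method tidy hip_glmm
#' @export
tidy.hip_glmm <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = 2 * pnorm(-abs(x$beta / x$se)),
    odds.ratio = exp(unname(x$beta)),
    conf.low = exp(unname(x$beta - z * x$se)),
    conf.high = exp(unname(x$beta + z * x$se))
  )
}

#' @rdname tidy.hip_glmm
#' @method tidy hip_cr_fit
#' @export
tidy.hip_cr_fit <- function(x, conf.level = 0.95, ...) {
  tidy.hip_glmm(x, conf.level = conf.level, ...)
}

#' Model-level summary of a fitted multilevel logistic model
#'
#' @param x A `hip_glmm` or `hip_cr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, random-intercept variances,
#'   convergence flag and the grouping sizes.
#' @method glance hip_glmm
#' @export
glance.hip_glmm <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    sigma2_cohort = x$sigma_cohort^2,
    sigma2_individual = x$sigma_individual^2,
    converged = x$converged,
    nobs = x$n_obs,
    n_individuals = x$n_individuals,
    n_cohorts = x$n_cohorts
  )
}

#' @rdname glance.hip_glmm
#' @method glance hip_cr_fit
#' @export
glance.hip_cr_fit <- function(x, ...) {
  glance.hip_glmm(x, ...)
}
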