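#' Natural cubic spline basis for baseline age
#'
#' Thin wrapper over [splines::ns()] producing the `df`-column natural
#' cubic spline basis used to model the non-linear age effect: interior
#' knots at the quantile terciles (for `df = 3`) and boundary knots at the
#' observed range, with linearity constraints beyond the boundaries. The
#' intercept plus the basis reproduces any linear function of age exactly
#' inside the boundary knots.
#'
#' @param x Numeric vector (baseline age in years).
#' @param df Degrees of freedom (number of basis columns).
#' @param knots Optional interior knots; defaults to quantiles of `x`.
#' @param boundary_knots Optional boundary knots; defaults to `range(x)`.
#' @return A numeric matrix with `df` columns carrying the knot attributes
#'   needed to evaluate the same basis on new data.
#' @export
spline_basis <- function(x, df = 3, knots = NULL, boundary_knots = NULL) {
  if (length(unique(x[is.finite(x)])) < df + 1) {
    abort(sprintf("Need at least %d distinct finite values for a %d-df spline.",
                  df + 1, df))
  }
  if (is.null(boundary_knots)) boundary_knots <- range(x, na.rm = TRUE)
  if (is.null(knots)) {
    probs <- seq_len(df - 1) / df
    knots <- unname(quantile(x, probs, na.rm = TRUE))
  }
  splines::ns(x, knots = knots, Boundary.knots = boundary_knots)
}

# Gauss-Hermite nodes and log-weights for weight function exp(-z^2)
# (Golub-Welsch: eigen-decomposition of the Jacobi matrix).
gauss_hermite <- function(k) {
  if (k == 1) return(list(nodes = 0, logw = 0.5 * log(pi)))
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       logw = log(pi) / 2 + 2 * log(abs(e$vectors[1, ord])))
}

#' Marginal log-likelihood of the nested logistic mixed model
#'
#' Evaluates the marginal likelihood of a logistic regression with nested
#' random intercepts (individual within cohort) by nested adaptive
#' Gauss-Hermite quadrature: the cohort-level integral is centred on the
#' profile mode of each cohort's offset, and each individual-level integral
#' on that individual's conditional mode. One point per level gives the
#' Laplace approximation. A zero standard deviation drops that level's
#' integral exactly.
#'
#' @param y 0/1 outcome vector.
#' @param X Design matrix (rows aligned with `y`).
#' @param cohort,individual Grouping vectors (any type; converted to
#'   factors). Individuals must be nested within cohorts.
#' @param beta Fixed-effect coefficients, length `ncol(X)`.
#' @param sigma_cohort,sigma_individual Random-intercept standard
#'   deviations (>= 0).
#' @param quadrature_points Integer vector of length 2 (cohort-level,
#'   individual-level nodes) or a scalar used for both.
#' @param gradient Also return the score vector
#'   (`c(beta, sigma_cohort, sigma_individual)` order)?
#' @return A list with `loglik` and optionally `gradient`.
#' @export
glmm_marginal_loglik <- function(y, X, cohort, individual, beta,
                                 sigma_cohort, sigma_individual,
                                 quadrature_points = c(7, 7),
                                 gradient = FALSE) {
  idx <- build_group_index(cohort, individual)
  X <- as.matrix(X)
  res <- glmm_nested_loglik_cpp(
    beta, sigma_cohort, sigma_individual,
    X[idx$order, , drop = FALSE], as.numeric(y[idx$order]),
    idx$ind_ptr, idx$coh_ptr,
    idx_gh(quadrature_points, 1)$nodes, idx_gh(quadrature_points, 1)$logw,
    idx_gh(quadrature_points, 2)$nodes, idx_gh(quadrature_points, 2)$logw,
    gradient
  )
  res
}

idx_gh <- function(quadrature_points, which) {
  k <- rep_len(as.integer(quadrature_points), 2)[which]
  if (k < 1) abort("quadrature_points must be >= 1.")
  gauss_hermite(k)
}

# Sort rows by (cohort, individual) and build CSR-style pointers.
build_group_index <- function(cohort, individual) {
  cohort <- as.character(cohort)
  individual <- paste(cohort, as.character(individual), sep = "\r")
  ord <- order(cohort, individual)
  coh_s <- cohort[ord]
  ind_s <- individual[ord]
  ind_change <- c(TRUE, ind_s[-1] != ind_s[-length(ind_s)])
  ind_starts <- which(ind_change)
  ind_ptr <- c(ind_starts - 1L, length(ind_s))
  coh_of_ind <- coh_s[ind_starts]
  coh_change <- c(TRUE, coh_of_ind[-1] != coh_of_ind[-length(coh_of_ind)])
  coh_ptr <- c(which(coh_change) - 1L, length(coh_of_ind))
  list(order = ord, ind_ptr = as.integer(ind_ptr),
       coh_ptr = as.integer(coh_ptr),
       n_individuals = length(ind_starts),
       n_cohorts = sum(coh_change))
}

# Build the fixed-effect design for the incident-RHOA models.
# Returns list(X, y, cohort, individual, meta) on the analysis rows.
build_glmm_design <- function(data, exposure = c("moderate", "severe"),
                              spline_df = 3,
                              moderate_threshold = 40, severe_threshold = 45) {
  exposure <- match.arg(exposure)
  data <- as_tibble(data)
  if (exposure == "severe") {
    data <- dplyr::filter(
      data,
      !(.data$lcea_deg >= moderate_threshold & .data$lcea_deg < severe_threshold))
    pincer <- as.numeric(data$lcea_deg >= severe_threshold)
  } else {
    pincer <- as.numeric(data$lcea_deg >= moderate_threshold)
  }

  ns_basis <- spline_basis(data$age_years, df = spline_df)
  cols <- list("(Intercept)" = rep(1, nrow(data)), pincer = pincer)
  for (j in seq_len(ncol(ns_basis))) {
    cols[[paste0("ns_age", j)]] <- ns_basis[, j]
  }
  cols$sex_male <- as.numeric(data$sex == "male")
  cols$bmi <- data$bmi_kg_m2
  has_pop <- "population_type" %in% names(data) &&
    length(unique(data$population_type)) > 1
  if (has_pop) cols$population_closed <- as.numeric(data$population_type == "closed")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  list(X = X, y = as.numeric(data$followup_grade == 2),
       cohort = data$cohort_id, individual = data$individual_id,
       data = data, exposure = exposure,
       ns_knots = attr(ns_basis, "knots"),
       ns_boundary = attr(ns_basis, "Boundary.knots"),
       age_mean = mean(data$age_years), bmi_mean = mean(data$bmi_kg_m2),
       has_pop = has_pop)
}

# Core optimiser shared by the binary and continuation-ratio fits.
# sigma_fixed: named numeric, e.g. c(cohort = 0) to pin a level's SD.
fit_glmm_core <- function(X, y, cohort, individual,
                          quadrature_points = c(7, 7),
                          sigma_start = c(0.3, 0.3), sigma_fixed = NULL,
                          tol = 1e-8, max_iter = 500, polish = TRUE) {
  idx <- build_group_index(cohort, individual)
  Xs <- as.matrix(X)[idx$order, , drop = FALSE]
  ys <- as.numeric(y)[idx$order]
  gh1 <- idx_gh(quadrature_points, 1)
  gh2 <- idx_gh(quadrature_points, 2)
  p <- ncol(Xs)

  # standardise non-binary, non-intercept columns for optimizer health
  centre <- rep(0, p); scale <- rep(1, p)
  for (j in seq_len(p)) {
    v <- Xs[, j]
    if (length(unique(v)) > 2) {
      centre[j] <- mean(v)
      s <- sd(v)
      if (s > 0) scale[j] <- s
    }
  }
  intercept_col <- which(apply(Xs, 2, function(v) all(v == 1)))[1]
  if (is.na(intercept_col)) {
    centre[] <- 0; scale[] <- 1
  }
  Xstd <- sweep(sweep(Xs, 2, centre), 2, scale, "/")
  if (!is.na(intercept_col)) Xstd[, intercept_col] <- 1

  fix_c <- !is.null(sigma_fixed) && "cohort" %in% names(sigma_fixed)
  fix_i <- !is.null(sigma_fixed) && "individual" %in% names(sigma_fixed)
  sc0 <- if (fix_c) sigma_fixed[["cohort"]] else sigma_start[1]
  si0 <- if (fix_i) sigma_fixed[["individual"]] else sigma_start[2]

  start_glm <- suppressWarnings(glm.fit(Xstd, ys, family = binomial()))
  theta0 <- c(start_glm$coefficients, sc0, si0)
  theta0[!is.finite(theta0)] <- 0

  free <- c(rep(TRUE, p), !fix_c, !fix_i)
  lower <- c(rep(-Inf, p), 0, 0)

  trace_env <- new.env()
  trace_env$vals <- numeric(0)

  expand <- function(th_free) {
    th <- theta0
    th[free] <- th_free
    th
  }
  eval_cpp <- function(th, grad) {
    glmm_nested_loglik_cpp(th[seq_len(p)], th[p + 1], th[p + 2],
                           Xstd, ys, idx$ind_ptr, idx$coh_ptr,
                           gh1$nodes, gh1$logw, gh2$nodes, gh2$logw, grad)
  }
  obj <- function(th_free) {
    th <- expand(th_free)
    ll <- eval_cpp(th, FALSE)$loglik
    trace_env$vals <- c(trace_env$vals, ll)
    -ll
  }
  gr_analytic <- function(th_free) {
    -eval_cpp(expand(th_free), TRUE)$gradient[free]
  }
  gr_numeric <- function(th_free) {
    # central differences on the objective, respecting the sigma >= 0 bounds
    vapply(seq_along(th_free), function(j) {
      h <- 1e-6 * (1 + abs(th_free[j]))
      up <- th_free; dn <- th_free
      up[j] <- up[j] + h
      dn[j] <- max(dn[j] - h, lower[free][j])
      (obj(up) - obj(dn)) / (up[j] - dn[j])
    }, numeric(1))
  }
  # The analytic score treats the adapted quadrature nodes as fixed; that
  # approximation is excellent for >= 3 nodes per active level but breaks
  # down for the pure Laplace case, where the ignored log-determinant term
  # matters. Fall back to numeric differentiation there.
  k2 <- rep_len(as.integer(quadrature_points), 2)
  active_c <- !(fix_c && sigma_fixed[["cohort"]] == 0)
  active_i <- !(fix_i && sigma_fixed[["individual"]] == 0)
  use_analytic <- (!active_c || k2[1] >= 3) && (!active_i || k2[2] >= 3)
  gr <- if (use_analytic) gr_analytic else gr_numeric

  opt <- nlminb(theta0[free], obj, gr, lower = lower[free],
                control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                               rel.tol = 1e-12, x.tol = 1e-10))

  # Polish with exact (numerically differenced) score: the fixed-node
  # analytic score is inconsistent with the adaptive objective by its
  # quadrature error, which can stall the first search a few hundredths
  # short of the optimum when the random-effect SDs are large.
  if (use_analytic && polish) {
    opt2 <- nlminb(opt$par, obj, gr_numeric, lower = lower[free],
                   control = list(iter.max = 50, eval.max = 200,
                                  rel.tol = 1e-12, x.tol = 1e-10))
    if (opt2$objective <= opt$objective) opt <- opt2
    final_grad <- gr_numeric(opt$par)
  } else {
    final_grad <- gr(opt$par)
  }

  # observed information via central differences of the score
  nf <- sum(free)
  H <- matrix(0, nf, nf)
  hstep <- 1e-5 * (1 + abs(opt$par))
  for (j in seq_len(nf)) {
    up <- opt$par; dn <- opt$par
    up[j] <- up[j] + hstep[j]
    dn[j] <- max(dn[j] - hstep[j], lower[free][j])
    d <- up[j] - dn[j]
    H[, j] <- (gr(up) - gr(dn)) / d
  }
  H <- (H + t(H)) / 2

  theta <- expand(opt$par)
  final <- eval_cpp(theta, FALSE)
  grad_norm <- sqrt(sum(final_grad^2))
  # Newton decrement: the parameter shift the remaining score implies on
  # the (standardised) optimisation scale; below 0.02 standard deviations
  # the fit is converged for every practical purpose.
  decrement <- tryCatch(
    max(abs(solve(H, final_grad))),
    error = function(e) Inf)
  converged <- opt$convergence == 0 || decrement < 0.02
  vcov_std <- tryCatch(solve(H), error = function(e) {
    warn("Observed information is singular; SEs use a pseudo-inverse.")
    ev <- eigen(H, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    ev$vectors[, pos, drop = FALSE] %*%
      ((1 / ev$values[pos]) * t(ev$vectors[, pos, drop = FALSE]))
  })

  # map standardised coefficients back to the original design scale
  beta_std <- theta[seq_len(p)]
  A <- diag(1 / scale, p)
  if (!is.na(intercept_col)) {
    A[intercept_col, ] <- -centre / scale
    A[intercept_col, intercept_col] <- 1
  }
  beta <- as.numeric(A %*% beta_std)
  names(beta) <- colnames(Xs)

  # embed into full-parameter covariance (fixed params get zero rows)
  vcov_full_std <- matrix(0, p + 2, p + 2)
  vcov_full_std[free, free] <- vcov_std
  Afull <- diag(p + 2)
  Afull[seq_len(p), seq_len(p)] <- A
  vcov_full <- Afull %*% vcov_full_std %*% t(Afull)
  dimnames(vcov_full) <- list(c(colnames(Xs), "sigma_cohort", "sigma_individual"),
                              c(colnames(Xs), "sigma_cohort", "sigma_individual"))

  list(beta = beta, se = sqrt(pmax(diag(vcov_full)[seq_len(p)], 0)),
       sigma_cohort = theta[p + 1], sigma_individual = theta[p + 2],
       sigma_se = sqrt(pmax(diag(vcov_full)[p + 1:2], 0)),
       vcov = vcov_full, loglik = final$loglik,
       converged = converged, newton_decrement = decrement,
       grad_norm = grad_norm, trace = trace_env$vals,
       n_obs = length(ys), n_individuals = idx$n_individuals,
       n_cohorts = idx$n_cohorts, quadrature_points = rep_len(quadrature_points, 2),
       message = opt$message)
}

#' Fit the multilevel logistic model for incident RHOA
#'
#' The one-stage individual-participant-data analysis model: a logistic
#' regression of incident definite RHOA (follow-up harmonised grade 2) on
#' a pincer-morphology indicator, adjusted for baseline age (natural cubic
#' spline, 3 df), biological sex and BMI (and open/closed population type
#' when present), with nested random intercepts for cohort and for
#' individual. Two hips of one person share the individual intercept; hip
#' side contributes no further random effect because a per-observation
#' intercept is unidentifiable in a binary model. The marginal likelihood
#' is maximised by quasi-Newton iteration over coefficients and
#' random-effect standard deviations, using nested adaptive Gauss-Hermite
#' quadrature (Laplace when `quadrature_points = 1`).
#'
#' @param data The included analysis set: columns `cohort_id`,
#'   `individual_id`, `followup_grade`, `lcea_deg`, `age_years`, `sex`,
#'   `bmi_kg_m2` and optionally `population_type`.
#' @param exposure `"moderate"` (LCEA >= 40) or `"severe"` (LCEA >= 45;
#'   hips with 40 <= LCEA < 45 are removed from the reference group).
#' @param quadrature_points Length-2 integer (cohort, individual nodes) or
#'   scalar; 1 = Laplace.
#' @param spline_df Degrees of freedom for the age spline.
#' @param sigma_fixed Optional named numeric to pin random-effect SDs,
#'   e.g. `c(cohort = 0, individual = 0)` collapses to plain logistic
#'   regression.
#' @param moderate_threshold,severe_threshold LCEA thresholds in degrees.
#' @param tol Gradient-norm tolerance reported with the fit.
#' @param max_iter Maximum optimiser iterations.
#' @param polish Follow the analytic-score search with a short
#'   numerically-differenced-score polish (recommended; disable for bulk
#'   simulation where speed matters more than the last few hundredths).
#' @return An object of class `hip_glmm`; see [tidy.hip_glmm()] and
#'   [glance.hip_glmm()].
#' @export
fit_binary_glmm <- function(data, exposure = c("moderate", "severe"),
                            quadrature_points = c(9, 9), spline_df = 3,
                            sigma_fixed = NULL,
                            moderate_threshold = 40, severe_threshold = 45,
                            tol = 1e-8, max_iter = 500, polish = TRUE) {
  des <- build_glmm_design(data, exposure, spline_df,
                           moderate_threshold, severe_threshold)
  fit <- fit_glmm_core(des$X, des$y, des$cohort, des$individual,
                       quadrature_points = quadrature_points,
                       sigma_fixed = sigma_fixed, tol = tol,
                       max_iter = max_iter, polish = polish)
  z <- qnorm(0.975)
  or_table <- tibble(
    term = names(fit$beta),
    estimate = fit$beta,
    std.error = fit$se,
    statistic = fit$beta / fit$se,
    p.value = 2 * pnorm(-abs(fit$beta / fit$se)),
    odds.ratio = exp(fit$beta),
    or.low = exp(fit$beta - z * fit$se),
    or.high = exp(fit$beta + z * fit$se)
  )
  structure(
    c(fit, list(or_table = or_table, exposure = des$exposure,
                spline_df = spline_df,
                ns_knots = des$ns_knots, ns_boundary = des$ns_boundary,
                age_mean = des$age_mean, bmi_mean = des$bmi_mean,
                has_pop = des$has_pop, outcome = "binary_definite")),
    class = "hip_glmm"
  )
}

#' @export
print.hip_glmm <- function(x, ...) {
  cat(sprintf("<hip_glmm> %s pincer exposure, %d hips / %d individuals / %d cohorts\n",
              x$exposure, x$n_obs, x$n_individuals, x$n_cohorts))
  cat(sprintf("  logLik %.3f | sigma_cohort %.3f, sigma_individual %.3f | %s\n",
              x$loglik, x$sigma_cohort, x$sigma_individual,
              if (x$converged) "converged" else "NOT converged"))
  pincer_row <- x$or_table[x$or_table$term == "pincer", ]
  if (nrow(pincer_row) == 1) {
    cat(sprintf("  pincer OR %.2f (95%% CI %.2f to %.2f)\n",
                pincer_row$odds.ratio, pincer_row$or.low, pincer_row$or.high))
  }
  invisible(x)
}
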