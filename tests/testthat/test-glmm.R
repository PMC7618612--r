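test_that("the natural spline basis reproduces linear functions and is natural", {
  age <- c(runif(200, 40, 90))
  B <- spline_basis(age, df = 3)
  expect_equal(ncol(B), 3)
  # least-squares projection of f(age) = age onto [1, basis]
  fit <- lm.fit(cbind(1, B), age)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # second derivative vanishes outside the boundary knots (linearity)
  grid <- seq(95, 120, by = 1)
  Bg <- splines::ns(grid, knots = attr(B, "knots"),
                    Boundary.knots = attr(B, "Boundary.knots"))
  second_diff <- apply(Bg, 2, function(col) diff(diff(col)))
  expect_lt(max(abs(second_diff)), 1e-10)
})

test_that("degenerate age vectors are rejected", {
  expect_error(spline_basis(rep(60, 50), df = 3), "distinct")
  expect_error(spline_basis(c(1, 2, 3), df = 3), "distinct")
})

test_that("AGHQ marginal likelihood matches brute-force integration on a toy set", {
  set.seed(42)
  m <- 10
  ind <- rep(1:m, each = 2)
  coh <- rep(rep(1:2, each = m / 2), each = 2)
  x <- rnorm(2 * m)
  X <- cbind(1, x)
  beta <- c(-0.5, 0.8); sc <- 0.6; si <- 0.9
  u <- rnorm(2, 0, sc); v <- rnorm(m, 0, si)
  y <- rbinom(2 * m, 1, plogis(X %*% beta + u[coh] + v[ind]))

  ours <- glmm_marginal_loglik(y, X, coh, ind, beta, sc, si,
                               quadrature_points = c(25, 25))
  brute <- brute_force_loglik(y, X, coh, ind, beta, sc, si)
  expect_equal(ours$loglik, brute, tolerance = 1e-6)
})

test_that("the score matches numerical differentiation of the marginal likelihood", {
  set.seed(7)
  n_ind <- 60
  coh <- rep(1:3, each = 40); ind <- rep(1:n_ind, each = 2)
  x <- rnorm(120); X <- cbind(1, x)
  y <- rbinom(120, 1, plogis(-0.5 + 0.5 * x))
  th <- c(-0.7, 0.4); sc <- 0.5; si <- 0.8
  g <- glmm_marginal_loglik(y, X, coh, ind, th, sc, si, c(9, 9),
                            gradient = TRUE)$gradient
  num <- vapply(1:4, function(j) {
    h <- 1e-6
    f <- function(d) {
      tt <- th; s1 <- sc; s2 <- si
      if (j <= 2) tt[j] <- tt[j] + d else if (j == 3) s1 <- s1 + d else s2 <- s2 + d
      glmm_marginal_loglik(y, X, coh, ind, tt, s1, s2, c(9, 9))$loglik
    }
    (f(h) - f(-h)) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-3)
})

test_that("with variances pinned at zero the fit collapses to plain logistic regression", {
  d <- quick_analysis_set(seed = 11, sigma_cohort = 0, sigma_individual = 0,
                          baseline_intercept = -2)
  f <- fit_binary_glmm(d, sigma_fixed = c(cohort = 0, individual = 0))
  des <- pincer:::build_glmm_design(d, "moderate")
  irls <- glm.fit(des$X, des$y, family = binomial())
  expect_lt(max(abs(f$beta - irls$coefficients)), 1e-4)
  expect_true(f$converged)
})

test_that("Laplace and higher-order quadrature agree on a small dataset", {
  d <- quick_analysis_set(seed = 21, n_cohorts = 3, individuals_per_cohort = 80,
                          baseline_intercept = -1.5)
  f1 <- fit_binary_glmm(d, quadrature_points = 1)
  f9 <- fit_binary_glmm(d, quadrature_points = 9)
  expect_lt(abs(f1$loglik - f9$loglik) / abs(f9$loglik), 0.02)
  expect_equal(sign(f1$beta), sign(f9$beta))
})

test_that("the fitted likelihood agrees with lme4's Laplace fit", {
  skip_if_not_installed("lme4")
  d <- quick_analysis_set(seed = 31, n_cohorts = 4, individuals_per_cohort = 200,
                          baseline_intercept = -1.6)
  f <- fit_binary_glmm(d, quadrature_points = 1)
  des <- pincer:::build_glmm_design(d, "moderate")
  dd <- data.frame(y = des$y, des$X[, -1], cohort = des$cohort, ind = des$individual)
  form <- y ~ pincer + ns_age1 + ns_age2 + ns_age3 + sex_male + bmi +
    population_closed + (1 | cohort) + (1 | ind)
  m <- suppressWarnings(suppressMessages(
    lme4::glmer(form, data = dd, family = binomial)))
  # same approximation, independent implementations: near-identical optima
  expect_lt(abs(f$loglik - as.numeric(stats::logLik(m))), 0.05)
  expect_lt(max(abs(f$beta - lme4::fixef(m))), 0.05)
})

test_that("replicating the whole dataset doubles the log-likelihood, not the estimates", {
  d <- quick_analysis_set(seed = 41, n_cohorts = 3, individuals_per_cohort = 60,
                          baseline_intercept = -1.5)
  d2 <- dplyr::bind_rows(
    d, dplyr::mutate(d, cohort_id = paste0(cohort_id, "_copy"),
                     individual_id = paste0(individual_id, "_copy")))
  f1 <- fit_binary_glmm(d, quadrature_points = 9)
  f2 <- fit_binary_glmm(d2, quadrature_points = 9)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-3)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-2)
  expect_lt(abs(f1$sigma_individual - f2$sigma_individual), 1e-2)
})

test_that("log-likelihood never ends below its starting value", {
  d <- quick_analysis_set(seed = 51, n_cohorts = 3, individuals_per_cohort = 80)
  f <- fit_binary_glmm(d)
  expect_gte(f$loglik, f$trace[1])
  expect_equal(max(f$trace), f$loglik, tolerance = 1e-6)
})

test_that("without pairing the individual variance carries no information", {
  # One binary observation per individual cannot identify an
  # individual-level variance: the likelihood is flat along
  # (intercept, sigma_individual), so the free fit must not beat the
  # sigma_individual = 0 fit, and the exposure effect must not move.
  d <- quick_analysis_set(seed = 61, n_cohorts = 4, individuals_per_cohort = 250,
                          sigma_individual = 0, baseline_intercept = -2)
  d$individual_id <- paste0(d$individual_id, "_", d$side)  # break the pairing
  f_free <- fit_binary_glmm(d, quadrature_points = 5)
  f_zero <- fit_binary_glmm(d, quadrature_points = 5,
                            sigma_fixed = c(individual = 0))
  expect_lt(2 * abs(f_free$loglik - f_zero$loglik), qchisq(0.95, 1))
  expect_lt(abs(f_free$beta["pincer"] - f_zero$beta["pincer"]), 0.05)
})

test_that("tidy and glance return the broom-shaped summaries", {
  d <- quick_analysis_set(seed = 71, n_cohorts = 3, individuals_per_cohort = 80)
  f <- fit_binary_glmm(d, quadrature_points = 5)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "odds.ratio",
                    "conf.low", "conf.high") %in% names(td)))
  expect_true("pincer" %in% td$term)
  expect_equal(td$odds.ratio, exp(td$estimate))
  gl <- glance(f)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$sigma2_individual, f$sigma_individual^2)
})

test_that("the severe-pincer model drops borderline hips from the reference group", {
  d <- quick_analysis_set(seed = 81, n_cohorts = 3, individuals_per_cohort = 100)
  des <- pincer:::build_glmm_design(d, "severe")
  borderline <- sum(d$lcea_deg >= 40 & d$lcea_deg < 45)
  expect_equal(nrow(des$X), nrow(d) - borderline)
  expect_true(all(des$X[, "pincer"] %in% 0:1))
})
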