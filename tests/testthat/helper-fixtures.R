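# Shared fixtures built in code.

# A small filtered analysis set for model tests; binary outcome mode makes
# the definite-RHOA model well-specified.
quick_analysis_set <- function(seed = 1, n_cohorts = 4,
                               individuals_per_cohort = 150, ...) {
  cfg <- cohort_sim_config(n_cohorts = n_cohorts,
                           individuals_per_cohort = individuals_per_cohort,
                           outcome_model = "binary", ...,
                           seed = seed)
  apply_filters(generate_cohorts(cfg))$data
}

# Minimal well-formed hip record used by the pipeline tests.
base_record <- function(n = 1) {
  tibble::tibble(
    cohort_id = "C01", individual_id = sprintf("I%04d", seq_len(n)),
    side = "left", age_years = 60, sex = "female", bmi_kg_m2 = 27,
    baseline_grade = 0L, followup_grade = 0L, followup_interval_years = 6,
    lcea_deg = 36, wcea_deg = 33, qc_pass = TRUE,
    radiograph_kind = "ap_pelvic", population_type = "open"
  )
}

# Independent brute-force minimiser of the geometric circle loss:
# coarse grid around the centroid followed by Nelder-Mead.
brute_force_circle <- function(pts) {
  loss <- function(par) {
    d <- sqrt((pts[, 1] - par[1])^2 + (pts[, 2] - par[2])^2)
    sum((d - par[3])^2)
  }
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  r0 <- mean(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2))
  grid <- expand.grid(x = cx + seq(-r0, r0, length.out = 11),
                      y = cy + seq(-r0, r0, length.out = 11))
  grid$r <- apply(grid, 1, function(g) {
    mean(sqrt((pts[, 1] - g[1])^2 + (pts[, 2] - g[2])^2))
  })
  vals <- apply(grid, 1, loss)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- optim(best, loss, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  opt <- optim(opt$par, loss, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(center = opt$par[1:2], radius = opt$par[3], loss = opt$value)
}

# Brute-force marginal log-likelihood of the nested logistic mixed model by
# adaptive numerical integration (stats::integrate) over both random
# effects; tractable only for tiny datasets.
brute_force_loglik <- function(y, X, cohort, individual, beta,
                               sigma_c, sigma_i) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (c0 in unique(cohort)) {
    inds <- unique(individual[cohort == c0])
    g_ind <- function(i, u) {
      rows <- which(individual == i)
      f <- function(vv) {
        vapply(vv, function(v) {
          e <- eta[rows] + u + v
          exp(sum(y[rows] * e - log1p(exp(e)))) * dnorm(v, 0, sigma_i)
        }, numeric(1))
      }
      integrate(f, -8 * sigma_i, 8 * sigma_i,
                rel.tol = 1e-12, abs.tol = 0)$value
    }
    f_coh <- function(uu) {
      vapply(uu, function(u) {
        prod(vapply(inds, g_ind, numeric(1), u = u)) * dnorm(u, 0, sigma_c)
      }, numeric(1))
    }
    ll <- ll + log(integrate(f_coh, -8 * sigma_c, 8 * sigma_c,
                             rel.tol = 1e-12, abs.tol = 0)$value)
  }
  ll
}
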