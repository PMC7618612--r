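#' Construct 2x2 exposure-outcome tables from hip records
#'
#' Counts exposed/unexposed by outcome, overall or per stratum:
#' `a` = exposed with outcome, `b` = exposed without, `c` = unexposed with,
#' `d` = unexposed without. Exposure is moderate pincer morphology
#' (LCEA >= 40 degrees) or severe pincer morphology (LCEA >= 45 degrees);
#' the outcome is incident definite RHOA (follow-up harmonised grade 2).
#' For the severe definition, hips with 40 <= LCEA < 45 are dropped
#' entirely so the reference group is free of pincer morphology by any
#' definition.
#'
#' @param data The included analysis set, with `lcea_deg` and the outcome
#'   column.
#' @param exposure `"moderate"` or `"severe"`.
#' @param strata Optional character vector of grouping column names.
#' @param outcome_col Column holding the follow-up harmonised grade.
#' @param moderate_threshold,severe_threshold LCEA thresholds in degrees.
#' @return A tibble with any stratum columns plus integer columns
#'   `a`, `b`, `c`, `d` and `n`; empty strata yield a zero row flagged in
#'   `empty`.
#' @export
build_2x2 <- function(data, exposure = c("moderate", "severe"), strata = NULL,
                      outcome_col = "followup_grade",
                      moderate_threshold = 40, severe_threshold = 45) {
  exposure <- match.arg(exposure)
  data <- as_tibble(data)
  if (exposure == "severe") {
    data <- dplyr::filter(
      data,
      !(.data$lcea_deg >= moderate_threshold & .data$lcea_deg < severe_threshold))
    exposed <- data$lcea_deg >= severe_threshold
  } else {
    exposed <- data$lcea_deg >= moderate_threshold
  }
  outcome <- data[[outcome_col]] == 2

  count_one <- function(e, o) {
    tibble(a = sum(e & o), b = sum(e & !o), c = sum(!e & o), d = sum(!e & !o),
           n = length(e), empty = length(e) == 0L)
  }
  if (is.null(strata)) {
    return(count_one(exposed, outcome))
  }
  data$.exposed <- exposed
  data$.outcome <- outcome
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      a = sum(.data$.exposed & .data$.outcome),
      b = sum(.data$.exposed & !.data$.outcome),
      c = sum(!.data$.exposed & .data$.outcome),
      d = sum(!.data$.exposed & !.data$.outcome),
      n = dplyr::n(), empty = dplyr::n() == 0L,
      .groups = "drop"
    )
}

#' Assemble a 2x2 table from cell counts
#'
#' @param a,b,c,d Non-negative integer cell counts: exposed/outcome,
#'   exposed/no outcome, unexposed/outcome, unexposed/no outcome. Vectors
#'   are recycled row-wise (one row per stratum).
#' @return A tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  tab <- tibble(a = as.integer(a), b = as.integer(b),
                c = as.integer(c), d = as.integer(d))
  if (any(tab < 0, na.rm = TRUE) || anyNA(tab)) {
    abort("All four cell counts must be non-negative integers.")
  }
  dplyr::mutate(tab, n = .data$a + .data$b + .data$c + .data$d,
                empty = .data$n == 0L)
}

ci_z <- function(conf_level) qnorm(1 - (1 - conf_level) / 2)

#' Absolute risk from a 2x2 table
#'
#' The observed absolute risk (AR) of the outcome among exposed hips, with
#' a normal-approximation confidence interval
#' \eqn{AR \pm z \sqrt{AR(1-AR)/n}} truncated to \[0, 1\]. Two denominator
#' conventions are used in the published tables: `"stratum_total"` divides
#' the exposed events by all hips in the stratum (the subgroup table
#' convention) and `"exposed_only"` divides by the exposed hips (the
#' association table convention, e.g. 101/4894 = 2.1%).
#'
#' @param tab A 2x2 tibble from [build_2x2()] or [contingency_2x2()] (one
#'   row per stratum; extra columns are passed through).
#' @param denominator `"stratum_total"` or `"exposed_only"`.
#' @param conf_level Confidence level (default 0.95).
#' @return `tab` with columns `kind` (`"AR"`), `estimate`, `conf.low`,
#'   `conf.high` (proportions) appended.
#' @export
absolute_risk <- function(tab, denominator = c("stratum_total", "exposed_only"),
                          conf_level = 0.95) {
  denominator <- match.arg(denominator)
  n <- if (denominator == "stratum_total") tab$a + tab$b + tab$c + tab$d else tab$a + tab$b
  if (any(n == 0)) abort("Absolute risk is undefined for a zero denominator.")
  ar <- tab$a / n
  half <- ci_z(conf_level) * sqrt(ar * (1 - ar) / n)
  dplyr::mutate(as_tibble(tab),
                kind = "AR", denominator_mode = denominator,
                estimate = ar,
                conf.low = pmax(0, ar - half),
                conf.high = pmin(1, ar + half))
}

#' Relative risk from a 2x2 table
#'
#' The risk ratio \eqn{RR = (a/(a+b)) / (c/(c+d))}; the two risks are the
#' unconditional maximum likelihood estimates of the exposed and unexposed
#' outcome probabilities. The confidence interval is Wald on the log scale,
#' \eqn{\exp(\ln RR \pm z \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)})}, which
#' reproduces the published stratified intervals from the printed counts.
#' With no unexposed events the RR is infinite (flagged); with no exposed
#' events the point estimate is 0 and the interval uses a 0.5 continuity
#' correction (flagged). The p-value is a two-sided mid-p exact test on the
#' hypergeometric conditional distribution by default, or a chi-squared
#' test.
#'
#' @inheritParams absolute_risk
#' @param p_method `"midp"` (default) or `"chisq"`.
#' @return `tab` with `kind` (`"RR"`), `estimate`, `conf.low`, `conf.high`,
#'   `p.value` and `flag` columns appended.
#' @export
relative_risk <- function(tab, conf_level = 0.95, p_method = c("midp", "chisq")) {
  p_method <- match.arg(p_method)
  z <- ci_z(conf_level)
  one <- function(a, b, c, d) {
    if (a + b == 0 || c + d == 0) {
      return(tibble(estimate = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, p.value = NA_real_,
                    flag = "undefined_margin"))
    }
    flag <- ""
    if (c == 0) {
      est <- Inf
      lo <- hi <- NA_real_
      flag <- "no_unexposed_events"
    } else if (a == 0) {
      est <- 0
      ac <- a + 0.5; bc <- b + 0.5; cc <- c + 0.5; dc <- d + 0.5
      se <- sqrt(1 / ac - 1 / (ac + bc) + 1 / cc - 1 / (cc + dc))
      lrr <- log((ac / (ac + bc)) / (cc / (cc + dc)))
      lo <- exp(lrr - z * se); hi <- exp(lrr + z * se)
      flag <- "no_exposed_events"
    } else {
      est <- (a / (a + b)) / (c / (c + d))
      se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
      lo <- exp(log(est) - z * se); hi <- exp(log(est) + z * se)
    }
    p <- if (p_method == "midp") midp_exact(a, b, c, d) else chisq_p(a, b, c, d)
    tibble(estimate = est, conf.low = lo, conf.high = hi, p.value = p, flag = flag)
  }
  res <- purrr::pmap_dfr(tab[, c("a", "b", "c", "d")], function(a, b, c, d) one(a, b, c, d))
  dplyr::bind_cols(dplyr::mutate(as_tibble(tab), kind = "RR"), res)
}

# Two-sided mid-p exact test on the hypergeometric distribution conditional
# on both margins.
midp_exact <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (k == 0 || k == m1 + m2) return(1)
  lo_tail <- stats::phyper(a, m1, m2, k) - 0.5 * stats::dhyper(a, m1, m2, k)
  hi_tail <- 1 - stats::phyper(a - 1, m1, m2, k) - 0.5 * stats::dhyper(a, m1, m2, k)
  min(1, 2 * min(lo_tail, hi_tail))
}

chisq_p <- function(a, b, c, d) {
  suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE), correct = FALSE)$p.value
  )
}

#' Odds ratio from a 2x2 table
#'
#' The sample odds ratio \eqn{OR = ad/bc} with a Wald confidence interval
#' on the log scale. Zero cells trigger the Haldane-Anscombe 0.5
#' correction on all cells (flagged). Note that the published unadjusted
#' ORs come from the mixed model and need not equal the raw-table value.
#'
#' @inheritParams absolute_risk
#' @return `tab` with `kind` (`"OR"`), `estimate`, `conf.low`, `conf.high`
#'   and `flag` columns appended.
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  z <- ci_z(conf_level)
  one <- function(a, b, c, d) {
    flag <- ""
    if (min(a, b, c, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
      flag <- "haldane_correction"
    }
    est <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    tibble(estimate = est,
           conf.low = exp(log(est) - z * se),
           conf.high = exp(log(est) + z * se),
           flag = flag)
  }
  res <- purrr::pmap_dfr(tab[, c("a", "b", "c", "d")], function(a, b, c, d) one(a, b, c, d))
  dplyr::bind_cols(dplyr::mutate(as_tibble(tab), kind = "OR"), res)
}

#' Published stratified risk table, recomputed
#'
#' Rebuilds the published subgroup analysis from the printed counts: per
#' stratum the absolute risk of incident RHOA in hips with moderate pincer
#' morphology (stratum-total denominator) and the relative risk versus
#' non-pincer hips, as percentages/ratios rounded like the printed table.
#'
#' @param counts A stratified count table
#'   (`published_counts("stratified")` by default) with columns
#'   `n_total`, `n_pincer`, `n_rhoa`, `n_pincer_rhoa`.
#' @return A tibble with one row per stratum: the reconstructed 2x2 cells,
#'   `ar_pct`, `ar_low_pct`, `ar_high_pct` (one decimal) and `rr`,
#'   `rr_low`, `rr_high` (two decimals).
#' @export
stratified_risk_table <- function(counts = published_counts("stratified")) {
  counts <- as_tibble(counts)
  tab <- dplyr::mutate(
    counts,
    a = .data$n_pincer_rhoa,
    b = .data$n_pincer - .data$n_pincer_rhoa,
    c = .data$n_rhoa - .data$n_pincer_rhoa,
    d = .data$n_total - .data$n_pincer - (.data$n_rhoa - .data$n_pincer_rhoa)
  )
  ar_est <- absolute_risk(tab, denominator = "stratum_total")
  rr_est <- relative_risk(tab)
  dplyr::bind_cols(
    tab,
    tibble(
      ar_pct = round_half_up(100 * ar_est$estimate, 1),
      ar_low_pct = round_half_up(100 * ar_est$conf.low, 1),
      ar_high_pct = round_half_up(100 * ar_est$conf.high, 1),
      rr = round_half_up(rr_est$estimate, 2),
      rr_low = round_half_up(rr_est$conf.low, 2),
      rr_high = round_half_up(rr_est$conf.high, 2),
      p.value = rr_est$p.value
    )
  )
}
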