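#' Published consortium count tables
#'
#' Count tables transcribed from the published worldwide hip-OA consortium
#' analysis of pincer morphology and incident radiographic hip
#' osteoarthritis (18 935 included hips from nine prospective cohorts).
#' These are the printed aggregates, not patient-level data; the package
#' uses them to reproduce the published descriptive and stratified risk
#' arithmetic.
#'
#' * `"baseline"`: per-cohort baseline characteristics (hip counts, age and
#'   BMI mean/SD, male hips, moderate/severe pincer counts, incident
#'   definite RHOA by sex, open/closed population type).
#' * `"association"`: exposed/reference hip and event counts for the
#'   moderate (LCEA >= 40 degrees) and severe (LCEA >= 45 degrees) pincer
#'   definitions; the severe reference group already excludes hips with
#'   40 <= LCEA < 45.
#' * `"stratified"`: subgroup counts by age band, BMI band and biological
#'   sex (total hips, pincer hips, incident RHOA hips, pincer-and-RHOA
#'   hips).
#'
#' @param table One of `"baseline"`, `"association"`, `"stratified"`.
#' @return A tibble.
#' @export
published_counts <- function(table = c("baseline", "association", "stratified")) {
  table <- match.arg(table)
  file <- switch(table,
                 baseline = "cohort_baseline_counts.csv",
                 association = "pincer_association_counts.csv",
                 stratified = "pincer_stratified_counts.csv")
  path <- system.file("extdata", file, package = "pincer", mustWork = TRUE)
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Pooled prevalence and incidence arithmetic from baseline counts
#'
#' Computes, per cohort and pooled, the moderate and severe pincer
#' prevalence and the incident definite-RHOA proportion, as percentages
#' rounded half-up to one decimal (the convention of the printed tables).
#'
#' @param counts A baseline count table, as returned by
#'   `published_counts("baseline")` or assembled from
#'   [summarize_baseline()] output.
#' @return A tibble with one row per cohort plus a pooled row and columns
#'   `n_hips`, `pct_moderate_pincer`, `pct_severe_pincer`,
#'   `pct_incident_rhoa`.
#' @export
prevalence_summary <- function(counts = published_counts("baseline")) {
  counts <- as_tibble(counts)
  counts$n_incident <- counts$n_incident_male + counts$n_incident_female
  pooled <- dplyr::summarise(
    counts,
    cohort_id = "pooled",
    dplyr::across(c("n_hips", "n_moderate_pincer", "n_severe_pincer", "n_incident"), sum)
  )
  out <- dplyr::bind_rows(
    counts[, c("cohort_id", "n_hips", "n_moderate_pincer", "n_severe_pincer", "n_incident")],
    pooled
  )
  dplyr::transmute(
    out,
    cohort_id = .data$cohort_id,
    n_hips = .data$n_hips,
    pct_moderate_pincer = round_half_up(100 * .data$n_moderate_pincer / .data$n_hips, 1),
    pct_severe_pincer = round_half_up(100 * .data$n_severe_pincer / .data$n_hips, 1),
    pct_incident_rhoa = round_half_up(100 * .data$n_incident / .data$n_hips, 1)
  )
}
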