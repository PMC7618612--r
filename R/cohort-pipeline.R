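#' Apply the study inclusion cascade to hip-level records
#'
#' Filters a table of hip records down to the analysis set, applying the
#' exclusion criteria in a fixed order and recording a flow report (one row
#' per filter with before/removed/after counts). A record failing several
#' criteria is removed, and counted, at the first failing filter. The
#' filters, in order:
#'
#' 1. follow-up radiograph within the follow-up window (default 4-8 years,
#'    both ends inclusive);
#' 2. age, sex and BMI known at baseline;
#' 3. an original baseline OA score present;
#' 4. radiograph usable for automated measurement: QC passed and not an AP
#'    hip radiograph (single-hip films do not allow a pelvic horizontal
#'    reference line);
#' 5. an original follow-up OA score present;
#' 6. no acetabular dysplasia (Wiberg CEA strictly above the threshold);
#' 7. completely free of RHOA at baseline (harmonised grade 0).
#'
#' The filters are conjunctive predicates, so the final analysis set does
#' not depend on their order, only the per-step counts do.
#'
#' @param records A data frame of hip records with (at least) columns
#'   `followup_interval_years`, `age_years`, `sex`, `bmi_kg_m2`,
#'   `baseline_grade`, `followup_grade`, `wcea_deg`; optional `qc_pass`
#'   (assumed `TRUE` when absent) and `radiograph_kind` (assumed
#'   `"ap_pelvic"`).
#' @param followup_window Length-2 numeric, inclusive follow-up interval in
#'   years.
#' @param dysplasia_threshold Wiberg CEA boundary in degrees; hips with
#'   `wcea_deg <= dysplasia_threshold` (or missing) are excluded.
#' @return A list with `data` (the included records, as a tibble) and
#'   `flow` (a `flow_report` tibble with columns `filter`, `n_before`,
#'   `n_removed`, `n_after`).
#' @export
apply_filters <- function(records, followup_window = c(4, 8),
                          dysplasia_threshold = 25) {
  data <- as_tibble(records)
  filter_names <- c("followup_interval", "demographics_known",
                    "baseline_grade_known", "radiograph_usable",
                    "followup_grade_known", "no_dysplasia",
                    "rhoa_free_at_baseline")
  flow <- vector("list", length(filter_names))
  for (i in seq_along(filter_names)) {
    keep <- filter_predicate(filter_names[i], data,
                             followup_window, dysplasia_threshold)
    n_before <- nrow(data)
    data <- data[keep, , drop = FALSE]
    flow[[i]] <- tibble(filter = filter_names[i],
                        n_before = n_before,
                        n_removed = n_before - nrow(data),
                        n_after = nrow(data))
  }
  flow <- dplyr::bind_rows(flow)
  class(flow) <- c("flow_report", class(flow))
  list(data = data, flow = flow)
}

# Evaluate one named filter predicate on the current record subset.
filter_predicate <- function(filter_name, data,
                             followup_window, dysplasia_threshold) {
  n <- nrow(data)
  qc <- if ("qc_pass" %in% names(data)) data$qc_pass %in% TRUE else rep(TRUE, n)
  kind <- if ("radiograph_kind" %in% names(data)) data$radiograph_kind else rep("ap_pelvic", n)
  num_ok <- function(x) !is.na(x) & is.finite(x)
  switch(
    filter_name,
    followup_interval = num_ok(data$followup_interval_years) &
      data$followup_interval_years >= followup_window[1] &
      data$followup_interval_years <= followup_window[2],
    demographics_known = num_ok(data$age_years) & !is.na(data$sex) &
      num_ok(data$bmi_kg_m2),
    baseline_grade_known = !is.na(data$baseline_grade),
    radiograph_usable = qc & !is.na(kind) & kind != "ap_hip",
    followup_grade_known = !is.na(data$followup_grade),
    no_dysplasia = num_ok(data$wcea_deg) & data$wcea_deg > dysplasia_threshold,
    rhoa_free_at_baseline = !is.na(data$baseline_grade) & data$baseline_grade == 0,
    abort(sprintf("Unknown filter '%s'.", filter_name))
  )
}

#' @export
print.flow_report <- function(x, ...) {
  cat("<flow_report>\n")
  NextMethod()
}

#' Baseline characteristics per cohort
#'
#' Summarises the included analysis set per cohort plus a pooled row:
#' number of hips, mean (SD) baseline age and BMI, number (%) of male hips,
#' number (%) with moderate and severe pincer morphology and incident
#' definite RHOA counts by sex. With a single record the SD is undefined
#' and reported as 0 with `sd_degenerate = TRUE`.
#'
#' @param records The included analysis set; needs columns `cohort_id`,
#'   `age_years`, `sex`, `bmi_kg_m2`, `lcea_deg`, `followup_grade`.
#' @param moderate_threshold,severe_threshold Pincer thresholds in degrees.
#' @return A tibble, one row per cohort plus a `"pooled"` row.
#' @export
summarize_baseline <- function(records, moderate_threshold = 40,
                               severe_threshold = 45) {
  data <- as_tibble(records)
  one <- function(d, label) {
    n <- nrow(d)
    sd_deg <- n < 2
    tibble(
      cohort_id = label,
      n_hips = n,
      age_mean = mean(d$age_years),
      age_sd = if (sd_deg) 0 else sd(d$age_years),
      bmi_mean = mean(d$bmi_kg_m2),
      bmi_sd = if (sd_deg) 0 else sd(d$bmi_kg_m2),
      sd_degenerate = sd_deg,
      n_male = sum(d$sex == "male"),
      pct_male = 100 * mean(d$sex == "male"),
      n_moderate_pincer = sum(d$lcea_deg >= moderate_threshold),
      pct_moderate_pincer = 100 * mean(d$lcea_deg >= moderate_threshold),
      n_severe_pincer = sum(d$lcea_deg >= severe_threshold),
      pct_severe_pincer = 100 * mean(d$lcea_deg >= severe_threshold),
      n_incident_rhoa = sum(d$followup_grade == 2),
      pct_incident_rhoa = 100 * mean(d$followup_grade == 2),
      n_incident_male = sum(d$followup_grade == 2 & d$sex == "male"),
      n_incident_female = sum(d$followup_grade == 2 & d$sex == "female")
    )
  }
  per_cohort <- data |>
    dplyr::group_by(.data$cohort_id) |>
    dplyr::group_map(~ one(.x, .y$cohort_id[[1]])) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_cohort, one(data, "pooled"))
}
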