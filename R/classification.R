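#' Pincer morphology category from the LCEA
#'
#' Classifies lateral femoral head coverage: no pincer below the moderate
#' threshold, moderate pincer morphology at LCEA >= 40 degrees and severe
#' pincer morphology at LCEA >= 45 degrees (both boundaries inclusive).
#' The category is monotone in the angle.
#'
#' @param lcea_deg Numeric vector of LCEA values in degrees.
#' @param moderate_threshold,severe_threshold Category boundaries in
#'   degrees; must be strictly increasing.
#' @return A factor with levels `none`, `moderate_pincer`, `severe_pincer`.
#' @export
classify_pincer <- function(lcea_deg, moderate_threshold = 40,
                            severe_threshold = 45) {
  if (!(moderate_threshold < severe_threshold)) {
    abort("Thresholds must be strictly increasing.")
  }
  assert_finite(lcea_deg, "lcea_deg")
  out <- ifelse(lcea_deg >= severe_threshold, "severe_pincer",
                ifelse(lcea_deg >= moderate_threshold, "moderate_pincer", "none"))
  factor(out, levels = c("none", "moderate_pincer", "severe_pincer"))
}

#' Acetabular dysplasia from the Wiberg CEA
#'
#' Dysplasia (lateral undercoverage) is defined as a Wiberg centre edge
#' angle of 25 degrees or less, boundary inclusive. Dysplastic hips are
#' excluded from the study reference group.
#'
#' @param wcea_deg Numeric vector of Wiberg CEA values in degrees.
#' @param threshold Dysplasia boundary in degrees (inclusive).
#' @return Logical vector.
#' @export
classify_dysplasia <- function(wcea_deg, threshold = 25) {
  assert_finite(wcea_deg, "wcea_deg")
  wcea_deg <= threshold
}

#' Harmonise a cohort-specific OA grade to the 0/1/2 scheme
#'
#' Cohorts grade radiographic hip osteoarthritis (RHOA) on different
#' scales. All are harmonised to: 0 = free of RHOA (original score 0),
#' 1 = doubtful RHOA (original score 1) and 2 = definite RHOA
#' (Kellgren-Lawrence >= 2, modified Croft >= 2, modified OA score = 2, or
#' total hip replacement regardless of score).
#'
#' @param system Character vector: `"KL"` (scores 0-4), `"modified_croft"`
#'   (0-5) or `"modified_OA"` (0-2).
#' @param score Integer vector of original scores, valid for `system`.
#' @param thr Logical vector: total hip replacement.
#' @return Integer vector of harmonised grades in `{0, 1, 2}`.
#' @export
harmonize_grade <- function(system, score, thr = FALSE) {
  n <- max(length(system), length(score), length(thr))
  system <- rep_len(as.character(system), n)
  score <- rep_len(score, n)
  thr <- rep_len(as.logical(thr), n)

  ranges <- list(KL = 0:4, modified_croft = 0:5, modified_OA = 0:2)
  bad_sys <- !system %in% names(ranges)
  if (any(bad_sys)) {
    abort(sprintf("Unknown grading system: %s.",
                  paste(unique(system[bad_sys]), collapse = ", ")))
  }
  ok <- thr | mapply(function(s, sc) !is.na(sc) && sc %in% ranges[[s]], system, score)
  if (!all(ok)) {
    i <- which(!ok)[1]
    abort(sprintf("Score %s is out of range for system '%s'.",
                  as.character(score[i]), system[i]))
  }

  definite <- thr |
    (system == "KL" & score >= 2) |
    (system == "modified_croft" & score >= 2) |
    (system == "modified_OA" & score == 2)
  out <- ifelse(definite, 2L, ifelse(score >= 1, 1L, 0L))
  as.integer(out)
}

#' Add morphology columns to a hip measurement table
#'
#' Data-frame-first wrapper combining [classify_pincer()] and
#' [classify_dysplasia()]: appends the morphology category, moderate and
#' severe pincer indicators, the dysplasia indicator and a
#' `pincer_borderline` tag for hips with 40 <= LCEA < 45, which the
#' severe-pincer sensitivity analysis removes from its reference group.
#'
#' @param data A data frame with LCEA and Wiberg CEA columns.
#' @param lcea_col,wcea_col Column names (strings) holding the angles.
#' @param moderate_threshold,severe_threshold,dysplasia_threshold
#'   Classification boundaries in degrees.
#' @return `data` as a tibble with columns `morphology`, `pincer_moderate`,
#'   `pincer_severe`, `pincer_borderline`, `dysplasia` appended.
#' @export
classify_morphology <- function(data, lcea_col = "lcea_deg", wcea_col = "wcea_deg",
                                moderate_threshold = 40, severe_threshold = 45,
                                dysplasia_threshold = 25) {
  lcea <- data[[lcea_col]]
  wcea <- data[[wcea_col]]
  if (is.null(lcea)) abort(sprintf("Column '%s' not found.", lcea_col))
  keep <- is.finite(lcea)
  morph <- factor(rep(NA_character_, nrow(data)),
                  levels = c("none", "moderate_pincer", "severe_pincer"))
  morph[keep] <- classify_pincer(lcea[keep], moderate_threshold, severe_threshold)
  dys <- rep(NA, nrow(data))
  if (!is.null(wcea)) {
    kw <- is.finite(wcea)
    dys[kw] <- classify_dysplasia(wcea[kw], dysplasia_threshold)
  }
  dplyr::mutate(
    as_tibble(data),
    morphology = morph,
    pincer_moderate = ifelse(is.na(morph), NA,
                             morph %in% c("moderate_pincer", "severe_pincer")),
    pincer_severe = ifelse(is.na(morph), NA, morph == "severe_pincer"),
    pincer_borderline = ifelse(is.na(morph), NA, morph == "moderate_pincer"),
    dysplasia = dys
  )
}
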