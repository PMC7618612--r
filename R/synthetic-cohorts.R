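#' Configuration for the synthetic multi-cohort hip dataset
#'
#' Describes a consortium-style population with known statistical ground
#' truth: several cohorts of individuals contributing one or two hips,
#' LCEA values drawn from a Normal distribution whose default mean/SD
#' (36.45 / 5.47 degrees) are matched to the published pincer prevalences
#' (about 25.8% of hips at or above 40 degrees and 5.9% at or above 45),
#' and incident-RHOA outcomes generated from the same continuation-ratio /
#' logistic structure the modelling functions fit, with cohort- and
#' individual-level random intercepts.
#'
#' Outcome generation modes:
#' * `"continuation_ratio"` (default): step 1 draws doubtful-or-worse RHOA
#'   (Y >= 1) from a logistic model with intercept `cr_alpha1` and pincer
#'   effect `cr_pincer_effects[1]`; step 2 draws definite RHOA among
#'   those (Y = 2 | Y >= 1) with intercept `cr_alpha2` and pincer effect
#'   `cr_pincer_effects[2]`. Both steps share the random intercepts.
#' * `"binary"`: definite RHOA is drawn directly from a logistic model
#'   with intercept `baseline_intercept` and pincer log-odds ratios
#'   `log_or_moderate` (LCEA >= 40) plus an increment to `log_or_severe`
#'   for LCEA >= 45; doubtful RHOA is then assigned independently among
#'   the non-definite hips with probability `grade1_fraction`. This mode
#'   makes the binary definite-RHOA model exactly well-specified, which
#'   is what the parameter-recovery checks need.
#'
#' Default effect sizes are the published adjusted odds ratios (1.15 for
#' moderate, 1.50 for severe pincer morphology); default random-intercept
#' SDs are 0.5 (cohort) and 1.0 (individual). The intercepts are
#' calibrated so that the definite-RHOA incidence among hips free of RHOA
#' at baseline is about 1.9% and the doubtful-or-worse proportion about
#' 19%, as observed.
#'
#' @param n_cohorts Number of cohorts.
#' @param individuals_per_cohort Individuals per cohort.
#' @param p_both_hips Probability an individual contributes both hips.
#' @param lcea_mean,lcea_sd Marginal LCEA distribution (degrees).
#' @param lcea_icc Share of LCEA variance at the individual level (the
#'   two hips of one person are correlated).
#' @param wcea_offset_mean,wcea_offset_sd Wiberg CEA minus LCEA, degrees.
#' @param age_mean,age_sd,age_range Baseline age distribution (years),
#'   truncated to `age_range`.
#' @param p_female Proportion of female individuals.
#' @param bmi_mean,bmi_sd Baseline BMI distribution.
#' @param sigma_cohort,sigma_individual Random-intercept SDs.
#' @param beta_age,beta_male,beta_bmi Covariate effects on the outcome
#'   log-odds (age and BMI centred at their means).
#' @param beta_closed Additional log-odds for closed-population cohorts
#'   (the second half of the cohorts are closed).
#' @param outcome_model `"continuation_ratio"` or `"binary"`.
#' @param baseline_intercept,log_or_moderate,log_or_severe Binary-mode
#'   outcome parameters.
#' @param grade1_fraction Binary mode: probability a non-definite hip is
#'   graded doubtful at follow-up.
#' @param cr_alpha1,cr_alpha2,cr_pincer_effects Continuation-ratio-mode
#'   outcome parameters (the pincer indicator is LCEA >= 40).
#' @param baseline_grade_probs Probabilities of harmonised baseline grade
#'   0/1/2 (non-zero grades are later excluded by the inclusion cascade).
#' @param followup_range Follow-up interval range in years (uniform).
#' @param p_thr Probability a definite-RHOA outcome is recorded as a
#'   total hip replacement.
#' @param p_qc_fail,p_ap_hip,p_missing_bmi,p_missing_followup Artifact
#'   rates exercised by the inclusion cascade.
#' @param seed RNG seed; the generated table is reproducible from it.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_cohorts = 10, individuals_per_cohort = 1050, p_both_hips = 0.9,
    lcea_mean = 36.45, lcea_sd = 5.47, lcea_icc = 0.5,
    wcea_offset_mean = -3, wcea_offset_sd = 1.5,
    age_mean = 62.7, age_sd = 8.4, age_range = c(40, 90),
    p_female = 0.7, bmi_mean = 27.3, bmi_sd = 4.5,
    sigma_cohort = 0.5, sigma_individual = 1.0,
    beta_age = 0.03, beta_male = -0.3, beta_bmi = 0.02, beta_closed = -0.8,
    outcome_model = c("continuation_ratio", "binary"),
    baseline_intercept = -4.19, log_or_moderate = log(1.15),
    log_or_severe = log(1.5), grade1_fraction = 0.17,
    cr_alpha1 = -1.43, cr_alpha2 = -3.37,
    cr_pincer_effects = c(0.3, 0.8),
    baseline_grade_probs = c(0.9, 0.07, 0.03),
    followup_range = c(4, 8), p_thr = 0.1,
    p_qc_fail = 0.01, p_ap_hip = 0.02,
    p_missing_bmi = 0.01, p_missing_followup = 0.02,
    seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  stopifnot(n_cohorts >= 1, individuals_per_cohort >= 1,
            p_both_hips >= 0, p_both_hips <= 1,
            lcea_sd >= 0, sigma_cohort >= 0, sigma_individual >= 0,
            abs(sum(baseline_grade_probs) - 1) < 1e-8)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_sim_config")
}

#' Generate a synthetic multi-cohort hip table
#'
#' Draws a hip-level table from a [cohort_sim_config()]: cohorts,
#' individuals (one or two hips each), demographics, LCEA/Wiberg CEA with
#' within-person correlation, cohort-specific grading systems (cycling
#' Kellgren-Lawrence, modified Croft and modified OA score), original
#' baseline and follow-up scores, total-hip-replacement flags and the
#' harmonised grades, plus the artifact columns (QC, radiograph kind,
#' missingness) consumed by [apply_filters()]. All randomness flows from
#' `cfg$seed`; the same seed reproduces the table exactly.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A tibble, one row per hip, with attribute `"truth"` carrying
#'   the generating parameters.
#' @export
generate_cohorts <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_local_seed(cfg$seed, generate_cohorts_impl(cfg))
}

generate_cohorts_impl <- function(cfg) {
  n_ind <- cfg$n_cohorts * cfg$individuals_per_cohort
  cohort_id <- sprintf("C%02d", rep(seq_len(cfg$n_cohorts),
                                    each = cfg$individuals_per_cohort))
  individual_id <- sprintf("%s-I%05d", cohort_id, seq_len(n_ind))
  population_type <- ifelse(
    rep(seq_len(cfg$n_cohorts), each = cfg$individuals_per_cohort) <=
      ceiling(cfg$n_cohorts / 2), "open", "closed")
  grading_system <- c("KL", "modified_croft", "modified_OA")[
    (rep(seq_len(cfg$n_cohorts), each = cfg$individuals_per_cohort) - 1L) %% 3L + 1L]

  # individual-level draws
  age <- pmin(pmax(rnorm(n_ind, cfg$age_mean, cfg$age_sd),
                   cfg$age_range[1]), cfg$age_range[2])
  sex <- ifelse(runif(n_ind) < cfg$p_female, "female", "male")
  bmi <- pmax(rnorm(n_ind, cfg$bmi_mean, cfg$bmi_sd), 15)
  both <- runif(n_ind) < cfg$p_both_hips
  n_hips_ind <- ifelse(both, 2L, 1L)
  u_cohort <- rnorm(cfg$n_cohorts, 0, cfg$sigma_cohort)
  v_ind <- rnorm(n_ind, 0, cfg$sigma_individual)
  lcea_ind <- rnorm(n_ind, 0, sqrt(cfg$lcea_icc) * cfg$lcea_sd)
  followup <- runif(n_ind, cfg$followup_range[1], cfg$followup_range[2])

  # expand to hips
  idx <- rep(seq_len(n_ind), n_hips_ind)
  side <- unlist(lapply(n_hips_ind, function(k) {
    if (k == 2L) c("left", "right") else sample(c("left", "right"), 1L)
  }), use.names = FALSE)
  n_hip <- length(idx)
  lcea <- cfg$lcea_mean + lcea_ind[idx] +
    rnorm(n_hip, 0, sqrt(1 - cfg$lcea_icc) * cfg$lcea_sd)
  wcea <- lcea + rnorm(n_hip, cfg$wcea_offset_mean, cfg$wcea_offset_sd)
  coh_idx <- rep(seq_len(cfg$n_cohorts),
                 each = cfg$individuals_per_cohort)[idx]

  pincer_mod <- as.numeric(lcea >= 40)
  pincer_sev <- as.numeric(lcea >= 45)
  eta_shared <- cfg$beta_age * (age[idx] - cfg$age_mean) +
    cfg$beta_male * (sex[idx] == "male") +
    cfg$beta_bmi * (bmi[idx] - cfg$bmi_mean) +
    cfg$beta_closed * (population_type[idx] == "closed") +
    u_cohort[coh_idx] + v_ind[idx]

  if (cfg$outcome_model == "binary") {
    eta2 <- cfg$baseline_intercept + cfg$log_or_moderate * pincer_mod +
      (cfg$log_or_severe - cfg$log_or_moderate) * pincer_sev + eta_shared
    definite <- rbinom(n_hip, 1, plogis(eta2))
    doubtful <- rbinom(n_hip, 1, cfg$grade1_fraction) * (1 - definite)
    grade_fu <- definite * 2L + doubtful
  } else {
    eta1 <- cfg$cr_alpha1 + cfg$cr_pincer_effects[1] * pincer_mod + eta_shared
    ge1 <- rbinom(n_hip, 1, plogis(eta1))
    eta2 <- cfg$cr_alpha2 + cfg$cr_pincer_effects[2] * pincer_mod + eta_shared
    eq2 <- rbinom(n_hip, 1, plogis(eta2)) * ge1
    grade_fu <- ge1 + eq2
  }

  grade_bl <- sample(0:2, n_hip, replace = TRUE, prob = cfg$baseline_grade_probs)
  thr <- grade_fu == 2L & runif(n_hip) < cfg$p_thr

  score_for <- function(system, grade, thr) {
    # an original-system score consistent with the harmonised grade
    score <- integer(length(grade))
    score[grade == 1L] <- 1L
    definite <- grade == 2L & !thr
    score[definite & system == "KL"] <-
      sample(2:4, sum(definite & system == "KL"), replace = TRUE)
    score[definite & system == "modified_croft"] <-
      sample(2:5, sum(definite & system == "modified_croft"), replace = TRUE)
    score[definite & system == "modified_OA"] <- 2L
    score
  }
  sys <- grading_system[idx]
  baseline_score <- score_for(sys, grade_bl, rep(FALSE, n_hip))
  followup_score <- score_for(sys, grade_fu, thr)

  out <- tibble(
    cohort_id = cohort_id[idx],
    individual_id = individual_id[idx],
    side = side,
    age_years = age[idx],
    sex = sex[idx],
    bmi_kg_m2 = ifelse(runif(n_hip) < cfg$p_missing_bmi, NA_real_, bmi[idx]),
    population_type = population_type[idx],
    radiograph_kind = ifelse(runif(n_hip) < cfg$p_ap_hip, "ap_hip", "ap_pelvic"),
    qc_pass = runif(n_hip) >= cfg$p_qc_fail,
    lcea_deg = lcea,
    wcea_deg = wcea,
    grading_system = sys,
    baseline_score = baseline_score,
    baseline_thr = FALSE,
    baseline_grade = harmonize_grade(sys, baseline_score, FALSE),
    followup_score = followup_score,
    thr = thr,
    followup_grade = ifelse(runif(n_hip) < cfg$p_missing_followup,
                            NA_integer_,
                            harmonize_grade(sys, followup_score, thr)),
    followup_interval_years = followup[idx]
  )
  attr(out, "truth") <- unclass(cfg)
  out
}
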