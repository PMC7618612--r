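test_that("2x2 construction counts exposure by outcome, with severe reference exclusion", {
  d <- tibble::tibble(
    lcea_deg = c(35, 41, 44, 46, 50, 30, 38, 42),
    followup_grade = c(0, 2, 0, 2, 0, 0, 2, 0),
    sex = c("f", "f", "m", "m", "f", "m", "f", "m")
  )
  mod <- build_2x2(d, "moderate")
  expect_equal(c(mod$a, mod$b, mod$c, mod$d), c(2, 3, 1, 2))

  sev <- build_2x2(d, "severe")
  # hips with 40 <= LCEA < 45 (rows 2, 3, 8) are dropped entirely
  expect_equal(sev$n, 5)
  expect_equal(c(sev$a, sev$b, sev$c, sev$d), c(1, 1, 1, 2))

  # stratified tables partition the pooled table
  by_sex <- build_2x2(d, "moderate", strata = "sex")
  expect_equal(sum(by_sex$a), mod$a)
  expect_equal(sum(by_sex$d), mod$d)
})

test_that("no exposed records yields zero exposed cells", {
  d <- tibble::tibble(lcea_deg = c(30, 35), followup_grade = c(0, 2))
  t <- build_2x2(d, "moderate")
  expect_equal(c(t$a, t$b), c(0, 0))
})

test_that("absolute risk reproduces the published arithmetic in both denominator modes", {
  # subgroup-table convention: events over all hips in the stratum
  t1 <- contingency_2x2(16, 291, 24, 1203)
  ar <- absolute_risk(t1, "stratum_total")
  expect_equal(ar$estimate, 16 / 1534, tolerance = 1e-12)
  expect_equal(round(100 * ar$estimate, 1), 1.0)
  expect_equal(round(100 * ar$conf.low, 1), 0.5)
  expect_equal(round(100 * ar$conf.high, 1), 1.6)
  # association-table convention: events over exposed hips
  t2 <- contingency_2x2(101, 4894 - 101, 251, 13790)
  expect_equal(round(100 * absolute_risk(t2, "exposed_only")$estimate, 1), 2.1)
  # identity: stratum-total AR times stratum size gives back the cell count
  expect_equal(absolute_risk(t1, "stratum_total")$estimate * t1$n, 16)
})

test_that("absolute risk handles zero events and zero denominators", {
  t0 <- contingency_2x2(0, 100, 0, 100)
  ar <- absolute_risk(t0, "stratum_total")
  expect_equal(ar$estimate, 0)
  expect_equal(ar$conf.low, 0)
  expect_equal(ar$conf.high, 0)
  expect_error(absolute_risk(contingency_2x2(0, 0, 0, 0)), "zero denominator")
})

test_that("relative risk matches the published stratified estimates and CIs", {
  rr1 <- relative_risk(contingency_2x2(16, 291, 24, 1203))
  expect_equal(round(rr1$estimate, 2), 2.66)
  expect_equal(round(rr1$conf.low, 2), 1.43)
  expect_equal(round(rr1$conf.high, 2), 4.95)

  rr2 <- relative_risk(contingency_2x2(47, 1316, 102, 4715))
  expect_equal(round(rr2$estimate, 2), 1.63)
  expect_equal(round(rr2$conf.low, 2), 1.16)
  expect_equal(round(rr2$conf.high, 2), 2.29)
})

test_that("relative risk is 1 under the null and flags zero-cell margins", {
  null <- relative_risk(contingency_2x2(10, 90, 20, 180))
  expect_equal(null$estimate, 1)
  expect_true(null$conf.low < 1 && null$conf.high > 1)

  inf <- relative_risk(contingency_2x2(5, 95, 0, 100))
  expect_equal(inf$estimate, Inf)
  expect_equal(inf$flag, "no_unexposed_events")

  zero <- relative_risk(contingency_2x2(0, 100, 5, 95))
  expect_equal(zero$estimate, 0)
  expect_equal(zero$flag, "no_exposed_events")
  expect_true(is.finite(zero$conf.low) && is.finite(zero$conf.high))
})

test_that("odds ratios follow the raw-table arithmetic", {
  or <- odds_ratio(contingency_2x2(31, 1090, 251, 13790))
  expect_equal(or$estimate, (31 * 13790) / (1090 * 251), tolerance = 1e-12)
  expect_equal(round(or$estimate, 2), 1.56)
  expect_equal(odds_ratio(contingency_2x2(1, 1, 1, 1))$estimate, 1)
  # symmetric case: a = d, b = c gives OR = (a/b)^2
  expect_equal(odds_ratio(contingency_2x2(6, 3, 3, 6))$estimate, 4)
  # zero cells use the Haldane-Anscombe correction and are flagged
  or0 <- odds_ratio(contingency_2x2(0, 10, 5, 10))
  expect_equal(or0$flag, "haldane_correction")
  expect_true(is.finite(or0$estimate))
})

test_that("point estimates are scale invariant while intervals tighten", {
  t1 <- contingency_2x2(16, 291, 24, 1203)
  t10 <- contingency_2x2(160, 2910, 240, 12030)
  rr1 <- relative_risk(t1); rr10 <- relative_risk(t10)
  expect_equal(rr1$estimate, rr10$estimate, tolerance = 1e-12)
  expect_lt(rr10$conf.high - rr10$conf.low, rr1$conf.high - rr1$conf.low)
  or1 <- odds_ratio(t1); or10 <- odds_ratio(t10)
  expect_equal(or1$estimate, or10$estimate, tolerance = 1e-12)
  expect_lt(or10$conf.high - or10$conf.low, or1$conf.high - or1$conf.low)
})

test_that("odds ratios approximate risk ratios for rare outcomes", {
  counts <- published_counts("stratified")
  tab <- dplyr::mutate(counts,
                       a = n_pincer_rhoa, b = n_pincer - n_pincer_rhoa,
                       c = n_rhoa - n_pincer_rhoa,
                       d = n_total - n_pincer - (n_rhoa - n_pincer_rhoa))
  rr <- relative_risk(tab)
  or <- odds_ratio(tab)
  risks <- pmax(tab$a / (tab$a + tab$b), tab$c / (tab$c + tab$d))
  rare <- risks < 0.02
  expect_gte(sum(rare), 3)
  expect_true(all(abs(or$estimate[rare] - rr$estimate[rare]) /
                    rr$estimate[rare] < 0.05))
})

test_that("the mid-p exact test is two-sided and bounded by 1", {
  p <- relative_risk(contingency_2x2(16, 291, 24, 1203))$p.value
  expect_true(p > 0 && p < 0.05)  # published p = 0.004 for this stratum
  p_null <- relative_risk(contingency_2x2(10, 90, 10, 90))$p.value
  expect_true(p_null <= 1 && p_null > 0.5)
  chisq <- relative_risk(contingency_2x2(16, 291, 24, 1203),
                         p_method = "chisq")$p.value
  expect_lt(chisq, 0.05)
})
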