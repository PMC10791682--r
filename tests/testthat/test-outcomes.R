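test_that("half-SD cutoff arithmetic", {
  expect_equal(half_sd_cutoffs(7, 2), c(low_cutoff = 6, high_cutoff = 8))
  expect_equal(half_sd_cutoffs(7.1, 1.6),
               c(low_cutoff = 6.3, high_cutoff = 7.9))
})

test_that("thresholds use per-gender sample moments, with an overall row for
           missing gender", {
  df <- make_cohort_df(6,
                       gender = c(rep("man", 3), rep("woman", 3)),
                       qol = c(5, 7, 9, 4, 6, 8))
  thr <- derive_thresholds(new_cohort(df), "qol")
  man <- thr[thr$group == "man", ]
  expect_equal(man$mean, 7); expect_equal(man$sd, 2)     # n-1 denominator
  expect_equal(man$low_cutoff, 6); expect_equal(man$high_cutoff, 8)
  expect_true("overall" %in% thr$group)
  expect_error(derive_thresholds(new_cohort(make_cohort_df(2)), "qol"),
               class = "wbi_threshold_error")
})

test_that("boundary semantics: at the low cutoff is low, at the high cutoff
           is not high, and the flags are mutually exclusive", {
  thr <- tibble::tibble(group = c("overall", "man", "woman"),
                        low_cutoff = 6, high_cutoff = 8, degenerate = FALSE)
  df <- make_cohort_df(4, qol = c(6, 8, 9, 5))
  flags <- classify_outcomes(new_cohort(df), qol_thresholds = thr,
                             fatigue_thresholds = thr)
  expect_equal(flags$low_qol, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(flags$high_qol, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(flags$low_qol & flags$high_qol))
})

test_that("no respondent is both low and high on a generated cohort", {
  gen <- generate_cohort(cohort_params(n = 3000, seed = 3))
  flags <- classify_outcomes(gen$cohort)
  expect_false(any(flags$low_qol & flags$high_qol))
  expect_false(any(flags$extreme_fatigue &
                     gen$cohort$fatigue > mean(gen$cohort$fatigue)))
})

test_that("zero-SD subgroups warn and classify nobody as low or high", {
  df <- make_cohort_df(5, gender = c("man", "man", "woman", "woman", "man"),
                       qol = 7)
  cohort <- new_cohort(df)
  expect_warning(thr <- derive_thresholds(cohort, "qol"), "degenerate")
  flags <- classify_outcomes(cohort, qol_thresholds = thr)
  expect_false(any(flags$low_qol) || any(flags$high_qol))
})

test_that("burnout is weekly-or-more symptoms on either domain", {
  df <- make_cohort_df(4,
                       ee = c("once a week", "never", "a few times a month",
                              "every day"),
                       dp = c("never", "a few times a week", "never", "never"))
  flags <- classify_outcomes(new_cohort(df))
  expect_equal(flags$burnout, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(flags$high_ee, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(flags$high_dp, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("intent-to-leave is positive from 'moderate' upwards only", {
  df <- make_cohort_df(5, itl = c("none", "slight", "moderate", "likely",
                                  "definite"))
  flags <- classify_outcomes(new_cohort(df))
  expect_equal(flags$itl_moderate_plus, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("prevalences cover all outcomes and satisfy the burnout
           decomposition", {
  gen <- generate_cohort(cohort_params(n = 5000, seed = 9))
  flags <- classify_outcomes(gen$cohort)
  prev <- outcome_prevalences(flags)
  expect_setequal(prev$outcome,
                  c("low_qol", "high_qol", "extreme_fatigue", "high_ee",
                    "high_dp", "burnout", "suicidal_ideation", "major_error",
                    "itl_moderate_plus"))
  p <- stats::setNames(prev$prevalence, prev$outcome)
  expect_gte(p[["burnout"]], max(p[["high_ee"]], p[["high_dp"]]))
  # an all-negative outcome has prevalence 0
  df <- make_cohort_df(4, si = "no")
  prev0 <- outcome_prevalences(classify_outcomes(new_cohort(df)))
  expect_equal(prev0$prevalence[prev0$outcome == "suicidal_ideation"], 0)
})

test_that("missing gender falls back to overall-cohort thresholds", {
  df <- make_cohort_df(7,
                       gender = c("man", "man", "man", "woman", "woman",
                                  "woman", NA),
                       qol = c(9, 9, 9, 2, 2, 2, 5))
  cohort <- new_cohort(df)
  # both gender subgroups are constant here, so they warn as degenerate;
  # the overall row (used for the missing-gender respondent) is not
  expect_warning(thr <- derive_thresholds(cohort, "qol"), "degenerate")
  flags <- classify_outcomes(cohort, qol_thresholds = thr)
  # overall mean 5.43, sd 3.31 -> low cutoff 3.78; respondent 7 has qol 5
  ov <- thr[thr$group == "overall", ]
  expect_equal(flags$low_qol[7], 5 <= ov$low_cutoff)
})

test_that("both published pretest presets are available and differ where the
           source report disagrees with itself", {
  foot <- pretest_presets("table_footnotes")
  text <- pretest_presets("results_text")
  expect_equal(unname(foot[["low_qol"]]), 0.273)
  expect_equal(unname(foot[["extreme_fatigue"]]), 0.332)
  expect_equal(unname(text[["extreme_fatigue"]]), 0.400)
  expect_equal(names(foot), names(text))
})
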