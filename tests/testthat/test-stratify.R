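fix <- table2_fixture()
low_tot <- score_table_totals(fix$low_qol)
high_tot <- score_table_totals(fix$high_qol)

test_that("score table construction reproduces the embedded counts and
           applies the open top bin", {
  ex <- expand_table(fix$low_qol)
  tab <- build_score_table(ex$scores, ex$outcome, top_bin = 7)
  expect_equal(tab$n_pos, fix$low_qol$n_pos)
  expect_equal(tab$n_neg, fix$low_qol$n_neg)
  expect_equal(unname(score_table_totals(tab)), c(163L, 434L))
  expect_equal(tab$label[10], ">=7")

  one <- build_score_table(c(5, 5), c(TRUE, FALSE))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$n_pos, one$n_neg), c(1L, 1L))

  merged <- build_score_table(c(7, 8, 9, 3), c(TRUE, TRUE, FALSE, FALSE),
                              top_bin = 7)
  expect_equal(merged$label, c("3", ">=7"))
  expect_equal(merged$n_pos[2], 2L)
  expect_equal(merged$n_neg[2], 1L)

  expect_error(build_score_table(1:3, c(TRUE, TRUE, TRUE)),
               class = "wbi_degenerate_error")
})

test_that("sparse-stratum combining pools low-event strata and is idempotent
           on dense tables", {
  # suicidal-ideation-like sparsity: 0-2 events in the low strata
  si <- wbiscreen:::new_score_table(
    lo = c(-2:6, 7), hi = c(-2:6, Inf),
    n_pos = c(0, 1, 1, 2, 5, 6, 7, 6, 4, 5),
    n_neg = c(48, 52, 60, 69, 76, 79, 63, 57, 34, 22))
  merged <- combine_sparse_strata(si, min_events = 5)
  expect_equal(merged$label[1], "-2 to 1")
  expect_equal(merged$n_pos[1], 4L)
  expect_equal(sum(merged$n_pos), sum(si$n_pos))
  expect_equal(sum(merged$n_neg), sum(si$n_neg))
  # the isolated sparse stratum at score 6 keeps its own row
  expect_true("6" %in% merged$label)
  # no two adjacent strata remain sparse
  sp <- merged$n_pos < 5
  expect_false(any(sp[-1] & sp[-length(sp)]))

  dense <- combine_sparse_strata(fix$low_qol, min_events = 1)
  expect_equal(dense$label, fix$low_qol$label)

  expect_warning(all_merged <- combine_sparse_strata(si, min_events = 100),
                 "single stratum")
  expect_equal(nrow(all_merged), 1)
})

test_that("stratum odds ratios and Woolf intervals match the published
           arithmetic", {
  lo2 <- stratum_odds_ratio(c(1, 47), low_tot)
  expect_equal(round_half_up(lo2$or, 2), 0.05)
  expect_equal(round_half_up(lo2$hi, 2), 0.37)
  hi1 <- stratum_odds_ratio(c(43, 10), high_tot)
  expect_equal(round_half_up(hi1$or, 2), 5.78)
  expect_equal(round_half_up(hi1$lo, 2), 2.85)
  expect_equal(round_half_up(hi1$hi, 2), 11.75)
  bal <- stratum_odds_ratio(c(10, 10), c(20, 20))
  expect_equal(bal$or, 1)
  zero <- stratum_odds_ratio(c(0, 5), c(10, 20))
  expect_true(zero$corrected)
  expect_gt(zero$or, 0)
})

test_that("exact-score likelihood ratios match the published arithmetic and
           zero cells are continuity-adjusted", {
  expect_equal(round_half_up(exact_score_lr(c(1, 47), low_tot)$lr, 2), 0.06)
  expect_equal(round_half_up(exact_score_lr(c(39, 9), high_tot)$lr, 2), 5.07)
  # a stratum holding everyone is uninformative
  expect_equal(exact_score_lr(c(163, 434), low_tot)$lr, 1)
  adj <- exact_score_lr(c(0, 10), c(50, 100))
  expect_true(adj$adjusted)
  expect_equal(adj$lr, (0.5 / 50) / (10 / 100))
  expect_error(exact_score_lr(c(0, 0), c(10, 10)),
               class = "wbi_degenerate_error")
})

test_that("likelihood ratios integrate to one over the negative-class score
           distribution", {
  set.seed(101)
  for (i in 1:25) {
    tab <- random_score_table(max_n = 60)
    if (any(tab$n_pos + tab$n_neg == 0)) next
    tot <- score_table_totals(tab)
    # only exact (unadjusted) LRs satisfy the identity
    if (any(tab$n_neg == 0 | tab$n_pos == 0)) next
    lrs <- vapply(seq_len(nrow(tab)), function(j)
      exact_score_lr(c(tab$n_pos[j], tab$n_neg[j]), tot)$lr, numeric(1))
    expect_equal(sum(lrs * tab$n_neg / tot[["N_neg"]]), 1, tolerance = 1e-12)
  }
})

test_that("posttest probability is a Bayes odds update", {
  expect_equal(round_half_up(100 * posttest_probability(0.273, 0.0567), 1),
               2.1)
  expect_equal(round_half_up(100 * posttest_probability(0.441, 15.87), 1),
               92.6)
  for (p in c(0.05, 0.273, 0.7)) {
    expect_equal(posttest_probability(p, 1), p)     # uninformative result
  }
  # strictly increasing in LR and pretest
  expect_true(all(diff(posttest_probability(0.3, c(0.1, 0.5, 1, 2, 10))) > 0))
  expect_gt(posttest_probability(0.4, 2), posttest_probability(0.2, 2))
  expect_error(posttest_probability(0, 2), class = "wbi_domain_error")
  expect_error(posttest_probability(1, 2), class = "wbi_domain_error")
})

test_that("threshold sensitivity/specificity and LR+ match the published
           threshold analysis", {
  ss <- sens_spec_at_threshold(fix$low_qol, 3)
  expect_equal(ss$sensitivity, 130 / 163)
  expect_equal(ss$specificity, 1 - 153 / 434)
  expect_equal(round_half_up(ss$lr_pos, 2), 2.26)
  expect_equal(sens_spec_at_threshold(fix$low_qol, -2)$sensitivity, 1)
  top <- sens_spec_at_threshold(fix$low_qol, 8)  # one above the top stratum
  expect_equal(top$sensitivity, 0)
  expect_equal(top$specificity, 1)
  expect_error(sens_spec_at_threshold(fix$low_qol, 20),
               class = "wbi_domain_error")
})

test_that("empirical AUC handles separation, identity and ties", {
  sep <- build_score_table(c(rep(9, 5), rep(-2, 5)),
                           c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(empirical_auc(sep), 1)
  same <- build_score_table(rep(c(1, 2), each = 4),
                            rep(c(TRUE, FALSE), 4))
  expect_equal(empirical_auc(same), 0.5)
  expect_equal(empirical_auc(fix$low_qol, direction = "low"),
               1 - empirical_auc(fix$low_qol))
})

test_that("AUC equals the brute-force pairwise oracle on random tables", {
  set.seed(77)
  for (i in 1:30) {
    tab <- random_score_table(max_n = 50)
    ex <- expand_table(tab)
    expect_equal(empirical_auc(tab),
                 auc_oracle(ex$scores[ex$outcome], ex$scores[!ex$outcome]))
  }
})

test_that("odds ratio converges to the likelihood ratio for rare strata", {
  # stratum holding a vanishing fraction of each class
  for (frac in c(0.05, 0.01, 0.001)) {
    N <- 1e5
    st <- c(round(2 * frac * N), round(frac * N))
    or <- stratum_odds_ratio(st, c(N, N))$or
    lr <- exact_score_lr(st, c(N, N))$lr
    expect_equal(or / lr, 1, tolerance = 4 * frac)
  }
})

test_that("risk-threshold selection finds the LR crossing", {
  expect_equal(select_threshold(fix$low_qol), 3)
  # two strata with the crossing at the upper one (LRs 0.06 and 2.88)
  two <- wbiscreen:::new_score_table(1:2, 1:2, c(2, 48), c(40, 20))
  expect_equal(select_threshold(two), 2)
  # decreasing LRs (a favorable outcome): no suffix stays above 1
  expect_true(is.na(select_threshold(fix$high_qol)))
  # across outcomes: the common threshold is the strictest one
  expect_equal(select_threshold(list(fix$low_qol, two)), 3)
})

test_that("ROC points are monotone in the threshold", {
  pts <- roc_points(fix$low_qol)
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
  expect_equal(pts$sensitivity[1], 1)
  expect_equal(pts$specificity[nrow(pts)], 1)
})
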