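test_that("Fisher exact p-values match direct hypergeometric enumeration", {
  expect_equal(fisher_exact(3, 1, 1, 3)$p_value, 34 / 70)
  expect_equal(fisher_exact(5, 0, 0, 5)$p_value, 2 / 252)
  expect_equal(fisher_exact(2, 2, 2, 2)$p_value, 1)
  # degenerate margins
  expect_equal(fisher_exact(0, 0, 3, 4)$p_value, 1)
  # agreement with the reference implementation on fixed tables
  for (tb in list(c(3, 1, 1, 3), c(10, 2, 3, 15), c(1, 9, 11, 3),
                  c(6, 6, 6, 6), c(0, 7, 5, 2))) {
    expect_equal(fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_value,
                 stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9, info = paste(tb, collapse = ","))
  }
})

test_that("chi-square test matches hand arithmetic and flags small expected
           counts", {
  expect_equal(chi_square_test(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_test(10, 10, 10, 10)$p_value, 1)
  t2 <- chi_square_test(20, 10, 10, 20)
  expect_equal(t2$statistic, 100 / 15, tolerance = 1e-12)
  expect_equal(t2$p_value,
               stats::pchisq(100 / 15, 1, lower.tail = FALSE))
  # expected counts exactly 5: the dispatch rule fires strictly below 5
  expect_false(chi_square_test(1, 9, 9, 1)$fisher_recommended)
  expect_true(chi_square_test(1, 9, 20, 3)$fisher_recommended)
  # transposition invariance
  expect_equal(chi_square_test(7, 3, 12, 18)$statistic,
               chi_square_test(7, 12, 3, 18)$statistic)
  expect_warning(chi_square_test(1, 1, 30, 1), "below 1")
})

test_that("contingency dispatch picks Fisher below expected count 5", {
  expect_equal(cont_table_test(3, 1, 1, 3)$method, "fisher_exact")
  expect_equal(cont_table_test(20, 20, 20, 20)$method, "chi_square")
})

test_that("Wilcoxon exact path matches enumeration; ties fall back to the
           corrected normal approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agreement with the reference implementation, exact, no ties
  set.seed(5)
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1:100, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied large-sample path vs reference normal approximation
  set.seed(6)
  x <- sample(0:5, 40, replace = TRUE)
  y <- sample(1:6, 35, replace = TRUE)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches hand computation and the k = 2 identity", {
  same <- kruskal_wallis_test(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  h <- kruskal_wallis_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(h$statistic, 32 / 7, tolerance = 1e-12)  # ranks 1..6
  expect_equal(h$p_value, stats::kruskal.test(
    list(c(1, 2), c(3, 4), c(5, 6)))$p.value)
  # with two groups, H equals the squared z of the uncorrected normal
  # approximation of the rank-sum test
  set.seed(8)
  x <- sample(0:8, 25, replace = TRUE); y <- sample(2:9, 30, replace = TRUE)
  kw <- kruskal_wallis_test(list(x, y))
  z2 <- stats::qnorm(stats::wilcox.test(x, y, exact = FALSE,
                                        correct = FALSE)$p.value / 2)^2
  expect_equal(kw$statistic, z2, tolerance = 1e-8)
})

test_that("Welch t test handles standard and degenerate inputs", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  set.seed(9)
  x <- rnorm(20, 1); y <- rnorm(25, 0, 2)
  ref <- stats::t.test(x, y)
  mine <- two_sample_t(x, y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value)
  expect_warning(deg <- two_sample_t(c(0, 0), c(1, 1)), "zero variance")
  expect_equal(deg$p_value, 0)
  expect_equal(two_sample_t(c(2, 2), c(2, 2))$p_value, 1)
})

test_that("group relabeling flips only the sign of t", {
  set.seed(10)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(two_sample_t(x, y)$statistic, -two_sample_t(y, x)$statistic)
  expect_equal(two_sample_t(x, y)$p_value, two_sample_t(y, x)$p_value)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcoxon_rank_sum(y, x)$p_value)
  expect_equal(fisher_exact(3, 8, 9, 2)$p_value, fisher_exact(9, 2, 3, 8)$p_value)
})

test_that("score separation between outcome groups mirrors the published
           group contrasts", {
  # the low-QOL fixture groups: means 4.10 vs 1.57, rank-sum p << 0.001
  ex <- expand_table(table2_fixture()$low_qol)
  x <- ex$scores[ex$outcome]; y <- ex$scores[!ex$outcome]
  expect_lt(wilcoxon_rank_sum(x, y)$p_value, 0.001)
  # burnout-vs-not summary moments (means 4.0 vs 1.0, SD ~2) at n 263/334
  set.seed(12)
  mk <- function(n, m, s) { v <- rnorm(n); m + s * scale(v)[, 1] }
  xb <- mk(263, 4.0, 2.0); yb <- mk(334, 1.0, 2.1)
  tt <- two_sample_t(xb, yb)
  expect_gt(abs(tt$statistic), 10)
  expect_lt(tt$p_value, 0.001)
})
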