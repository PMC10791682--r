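new_test_result <- function(statistic, p_value, method, df = NA_real_, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  out <- list(statistic = unname(statistic), p_value = min(unname(p_value), 1),
              method = method, df = unname(df), ...)
  class(out) <- "wbi_test"
  out
}

#' @export
print.wbi_test <- function(x, ...) {
  cat(sprintf("<wbi_test> %s: statistic = %s, df = %s, p = %.4g\n",
              x$method, format(x$statistic), format(x$df), x$p_value))
  invisible(x)
}

as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- as.vector(t(a))
    a <- m[1]; b <- m[2]; c <- m[3]; d <- m[4]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(cells >= 0), all(cells == round(cells)))
  cells
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass rule: with both margins fixed, the cell
#' `a` follows a hypergeometric distribution; the p-value sums the
#' probabilities of all tables whose point probability does not exceed that of
#' the observed table (relative tolerance 1e-12 on the comparison). A zero
#' margin makes the table degenerate and returns p = 1.
#'
#' @param a,b,c,d cell counts (row-wise: exposed+/outcome+, exposed+/outcome-,
#'   exposed-/outcome+, exposed-/outcome-); or a 2x2 matrix as `a`.
#' @return A `wbi_test` (statistic is the observed table probability).
#' @export
#' @examples
#' fisher_exact(3, 1, 1, 3)$p_value # 34/70
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  cl <- as_2x2(a, b, c, d)
  a <- cl[1]; b <- cl[2]; c <- cl[3]; d <- cl[4]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    return(new_test_result(1, 1, "fisher_exact"))
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  new_test_result(p_obs, p, "fisher_exact")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic without continuity correction, df = 1, p from the
#' chi-square upper tail. The result carries a `fisher_recommended` flag when
#' any expected cell count is below 5 (the usual "as appropriate" dispatch
#' rule; the rule fires strictly below 5); an expected count below 1
#' additionally raises a warning.
#'
#' @inheritParams fisher_exact
#' @return A `wbi_test` with field `fisher_recommended`.
#' @export
chi_square_test <- function(a, b = NULL, c = NULL, d = NULL) {
  cl <- as_2x2(a, b, c, d)
  m <- matrix(cl, 2, 2, byrow = TRUE)
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stopifnot(all(rowSums(m) > 0), all(colSums(m) > 0))
  if (any(expected < 1)) {
    warning("expected cell count below 1; Fisher exact test recommended")
  }
  stat <- sum((m - expected)^2 / expected)
  new_test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  "chi_square", df = 1,
                  fisher_recommended = any(expected < 5))
}

#' Contingency-test dispatch
#'
#' Applies the usual rule: Fisher exact test when any expected cell count is
#' below 5, Pearson chi-square otherwise. A zero margin returns the
#' degenerate Fisher result (p = 1).
#'
#' @inheritParams fisher_exact
#' @return A `wbi_test`.
#' @export
cont_table_test <- function(a, b = NULL, c = NULL, d = NULL) {
  cl <- as_2x2(a, b, c, d)
  m <- matrix(cl, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(fisher_exact(cl[1], cl[2], cl[3], cl[4]))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    fisher_exact(cl[1], cl[2], cl[3], cl[4])
  } else {
    chi_square_test(cl[1], cl[2], cl[3], cl[4])
  }
}

rank_tie_stats <- function(v) {
  r <- rank(v)                      # midranks
  t <- table(v)
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Wilcoxon rank-sum (Mann--Whitney) test
#'
#' Statistic is the Mann--Whitney U for the first group. Small samples
#' (`n_x + n_y <= 12`) without ties are handled by exact enumeration of all
#' rank assignments (two-sided p = twice the smaller tail, capped at 1);
#' otherwise a normal approximation with midranks, tie-corrected variance and
#' a 0.5 continuity correction is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   decides by the rule above.
#' @return A `wbi_test` with field `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- exact %||% (n <= 12 && !ties)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (use_exact && !ties) {
    combos <- utils::combn(n, n1)
    us <- colSums(matrix(seq_len(n)[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    return(new_test_result(u, p, "wilcoxon", exact = TRUE))
  }
  mu <- n1 * n2 / 2
  tie_term <- rank_tie_stats(c(x, y))$tie_term
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v == 0) return(new_test_result(u, 1, "wilcoxon", exact = FALSE))
  z <- (abs(u - mu) - 0.5) / sqrt(v)
  z <- max(z, 0)
  new_test_result(u, 2 * stats::pnorm(-z), "wilcoxon", exact = FALSE)
}

#' Kruskal--Wallis rank test
#'
#' H statistic on midranks with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`, df = k - 1, chi-square p-value.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A `wbi_test`.
#' @export
kruskal_wallis_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  all_v <- unlist(groups, use.names = FALSE)
  stopifnot(!anyNA(all_v))
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  ns <- lengths(groups)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  tie_term <- rank_tie_stats(all_v)$tie_term
  corr <- 1 - tie_term / (n^3 - n)
  if (corr == 0) return(new_test_result(0, 1, "kruskal_wallis",
                                        df = length(groups) - 1))
  h <- h / corr
  h <- max(h, 0)   # guard tiny negative from floating point
  df <- length(groups) - 1
  new_test_result(h, stats::pchisq(h, df = df, lower.tail = FALSE),
                  "kruskal_wallis", df = df)
}

#' Welch two-sample t test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided.
#' Degenerate inputs (zero variance in both groups) give p = 1 for equal
#' means and p = 0 with a warning otherwise.
#'
#' @param x,y numeric vectors of length at least 2.
#' @return A `wbi_test`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2, !anyNA(x), !anyNA(y))
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(new_test_result(0, 1, "t_test", df = n1 + n2 - 2))
    warning("zero variance in both groups with unequal means")
    return(new_test_result(sign(m1 - m2) * Inf, 0, "t_test",
                           df = n1 + n2 - 2))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  new_test_result(t_stat, 2 * stats::pt(-abs(t_stat), df = df),
                  "t_test", df = df)
}
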