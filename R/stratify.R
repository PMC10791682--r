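stratum_label <- function(lo, hi) {
  ifelse(is.infinite(hi), paste0(">=", lo),
         ifelse(lo == hi, as.character(lo), paste0(lo, " to ", hi)))
}

new_score_table <- function(lo, hi, n_pos, n_neg) {
  stopifnot(length(lo) == length(hi), length(lo) == length(n_pos),
            length(lo) == length(n_neg), all(n_pos >= 0), all(n_neg >= 0),
            !is.unsorted(lo, strictly = TRUE))
  out <- tibble::tibble(label = stratum_label(lo, hi), lo = as.numeric(lo),
                        hi = as.numeric(hi), n_pos = as.integer(n_pos),
                        n_neg = as.integer(n_neg))
  attr(out, "N_pos") <- sum(out$n_pos)
  attr(out, "N_neg") <- sum(out$n_neg)
  class(out) <- c("wbi_score_table", class(out))
  out
}

#' Totals of a score-stratum table
#'
#' @param table a `wbi_score_table`.
#' @return Named integer vector `c(N_pos =, N_neg =)`.
#' @export
score_table_totals <- function(table) {
  c(N_pos = attr(table, "N_pos"), N_neg = attr(table, "N_neg"))
}

#' @export
print.wbi_score_table <- function(x, ...) {
  cat(sprintf("<wbi_score_table> %d strata; N_pos = %d, N_neg = %d\n",
              nrow(x), attr(x, "N_pos"), attr(x, "N_neg")))
  NextMethod()
}

#' Cross-tabulate outcome status by exact score
#'
#' Builds the per-score stratum table underlying all stratum-specific
#' statistics: for each observed score level, the number of outcome-positive
#' and outcome-negative respondents. Scores at or above `top_bin` are merged
#' into a single open-ended stratum (the printed-table convention); set
#' `top_bin = NULL` for an unbinned table.
#'
#' @param scores integer score vector.
#' @param outcome logical vector, same length, `TRUE` = outcome present.
#' @param top_bin smallest score of the open-ended top stratum, or `NULL`.
#' @return A `wbi_score_table` tibble (`label`, `lo`, `hi`, `n_pos`, `n_neg`)
#'   with totals as attributes.
#' @export
build_score_table <- function(scores, outcome, top_bin = 7) {
  stopifnot(length(scores) == length(outcome), !anyNA(scores), !anyNA(outcome))
  outcome <- as.logical(outcome)
  if (all(outcome) || !any(outcome)) {
    stop_wbi("outcome must have both positive and negative respondents; ",
             "stratum statistics are undefined otherwise",
             class = "wbi_degenerate_error")
  }
  s <- as.numeric(scores)
  binned <- !is.null(top_bin) && any(s >= top_bin)
  key <- if (binned) pmin(s, top_bin) else s
  lev <- sort(unique(key))
  n_pos <- vapply(lev, function(l) sum(key == l & outcome), numeric(1))
  n_neg <- vapply(lev, function(l) sum(key == l & !outcome), numeric(1))
  hi <- lev
  if (binned) hi[length(hi)] <- Inf
  new_score_table(lev, hi, n_pos, n_neg)
}

#' Merge sparse score strata
#'
#' Pools each maximal run of *adjacent* strata that all hold fewer than
#' `min_events` outcome-positive respondents into a single stratum with a
#' range label (e.g. `"-2 to 1"`). An isolated sparse stratum between
#' well-populated neighbours is left alone (merging it with a dense
#' neighbour would dilute that neighbour's estimate), so after combining no
#' two adjacent strata are both sparse. A table already satisfying the
#' minimum everywhere is returned unchanged.
#'
#' @param table a `wbi_score_table`.
#' @param min_events sparsity cut: strata with fewer outcome-positive
#'   respondents than this are candidates for merging (default 5).
#' @return A `wbi_score_table` with the same totals.
#' @export
combine_sparse_strata <- function(table, min_events = 5) {
  stopifnot(inherits(table, "wbi_score_table"), min_events >= 1)
  if (attr(table, "N_pos") < min_events) {
    warning("fewer than min_events outcome-positive respondents in total; ",
            "collapsing to a single stratum")
    return(new_score_table(table$lo[1], table$hi[nrow(table)],
                           attr(table, "N_pos"), attr(table, "N_neg")))
  }
  sparse <- table$n_pos < min_events
  grp <- integer(nrow(table))
  g <- 0L
  for (i in seq_len(nrow(table))) {
    if (i == 1 || !(sparse[i] && sparse[i - 1])) g <- g + 1L
    grp[i] <- g
  }
  agg <- function(v, f) as.vector(tapply(v, grp, f))
  new_score_table(agg(table$lo, min), agg(table$hi, max),
                  agg(table$n_pos, sum), agg(table$n_neg, sum))
}

#' Stratum odds ratio with Woolf confidence interval
#'
#' Contrasts one score stratum against all other strata combined:
#' `a = n_pos`, `b = n_neg`, `c = N_pos - a`, `d = N_neg - b`,
#' `OR = ad / bc`, with the Woolf log-method 95% interval
#' `exp(log(OR) +- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' triggers the Haldane--Anscombe +0.5 correction to all four cells, flagged
#' in the result.
#'
#' @param stratum numeric `c(n_pos, n_neg)` for the stratum.
#' @param totals numeric `c(N_pos, N_neg)` for the whole table.
#' @param conf confidence level (default 0.95).
#' @return List `or`, `lo`, `hi`, `corrected`.
#' @export
#' @examples
#' stratum_odds_ratio(c(1, 47), c(163, 434)) # OR 0.05, upper 0.37
stratum_odds_ratio <- function(stratum, totals, conf = 0.95) {
  stratum <- unname(stratum); totals <- unname(totals)
  a <- stratum[1]; b <- stratum[2]
  cc <- totals[1] - a; d <- totals[2] - b
  stopifnot(a >= 0, b >= 0, cc >= 0, d >= 0)
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = or, lo = or * exp(-z * se), hi = or * exp(z * se),
       corrected = corrected)
}

#' Exact-score likelihood ratio with Katz confidence interval
#'
#' The stratum-specific (multi-level) likelihood ratio
#' `LR = P(score in stratum | outcome+) / P(score in stratum | outcome-)`
#' `= (n_pos/N_pos) / (n_neg/N_neg)`, with the Katz log-method interval for a
#' ratio of two binomial proportions:
#' `exp(log(LR) +- 1.96 * sqrt((1-p1)/(N_pos*p1) + (1-p2)/(N_neg*p2)))`.
#' A zero numerator or denominator count is continuity-adjusted to 0.5 events
#' (flagged); both zero is an error (the stratum carries no information).
#'
#' @param stratum numeric `c(n_pos, n_neg)`.
#' @param totals numeric `c(N_pos, N_neg)`, both positive.
#' @param conf confidence level (default 0.95).
#' @return List `lr`, `lo`, `hi`, `adjusted`.
#' @export
#' @examples
#' exact_score_lr(c(1, 47), c(163, 434)) # LR 0.06
exact_score_lr <- function(stratum, totals, conf = 0.95) {
  stratum <- unname(stratum); totals <- unname(totals)
  n_pos <- stratum[1]; n_neg <- stratum[2]
  N_pos <- totals[1]; N_neg <- totals[2]
  stopifnot(N_pos > 0, N_neg > 0, n_pos >= 0, n_neg >= 0,
            n_pos <= N_pos, n_neg <= N_neg)
  if (n_pos == 0 && n_neg == 0) {
    stop_wbi("likelihood ratio undefined: stratum has no respondents",
             class = "wbi_degenerate_error")
  }
  adjusted <- n_pos == 0 || n_neg == 0
  if (n_pos == 0) n_pos <- 0.5
  if (n_neg == 0) n_neg <- 0.5
  p1 <- n_pos / N_pos; p2 <- n_neg / N_neg
  lr <- p1 / p2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt((1 - p1) / (N_pos * p1) + (1 - p2) / (N_neg * p2))
  list(lr = lr, lo = lr * exp(-z * se), hi = lr * exp(z * se),
       adjusted = adjusted)
}

#' Bayes posttest probability
#'
#' Updates a pretest probability by a likelihood ratio on the odds scale:
#' `posttest = (odds * LR) / (1 + odds * LR)` with `odds = p / (1 - p)`.
#'
#' @param pretest pretest probability, strictly between 0 and 1.
#' @param lr likelihood ratio(s), `>= 0`; vectorized.
#' @return Posttest probabilities in \[0, 1\].
#' @export
#' @examples
#' posttest_probability(0.273, 0.0567) # ~0.021
posttest_probability <- function(pretest, lr) {
  if (!is.numeric(pretest) || length(pretest) != 1 ||
      pretest <= 0 || pretest >= 1) {
    stop_wbi("pretest probability must lie strictly between 0 and 1",
             class = "wbi_domain_error")
  }
  stopifnot(all(lr >= 0))
  odds <- pretest / (1 - pretest) * lr
  odds / (1 + odds)
}

table_top_score <- function(table) {
  max(ifelse(is.infinite(table$hi), table$lo, table$hi))
}

check_threshold <- function(table, threshold) {
  lo_min <- table$lo[1]
  hi_max <- table_top_score(table)
  if (threshold < lo_min || threshold > hi_max + 1) {
    stop_wbi("threshold ", threshold, " outside the observed score range",
             class = "wbi_domain_error")
  }
  splits <- table$lo < threshold & threshold <= ifelse(is.infinite(table$hi),
                                                       table$lo, table$hi)
  if (any(splits)) {
    stop_wbi("threshold ", threshold, " falls inside a combined stratum",
             class = "wbi_domain_error")
  }
}

#' Sensitivity, specificity and positive likelihood ratio at a threshold
#'
#' Treats score `>= threshold` as test-positive: sensitivity is
#' `P(score >= t | outcome+)`, specificity `P(score < t | outcome-)`, and
#' `LR+ = sensitivity / (1 - specificity)` with a Katz log interval.
#' `threshold` may be any stratum lower bound, or one above the maximum score
#' (giving sensitivity 0, specificity 1).
#'
#' @param table a `wbi_score_table`.
#' @param threshold score cut point.
#' @param conf confidence level for the LR+ interval.
#' @return List `sensitivity`, `specificity`, `lr_pos`, `lr_lo`, `lr_hi`.
#' @export
sens_spec_at_threshold <- function(table, threshold, conf = 0.95) {
  stopifnot(inherits(table, "wbi_score_table"))
  check_threshold(table, threshold)
  N_pos <- attr(table, "N_pos"); N_neg <- attr(table, "N_neg")
  pos_ge <- sum(table$n_pos[table$lo >= threshold])
  neg_ge <- sum(table$n_neg[table$lo >= threshold])
  sens <- pos_ge / N_pos
  spec <- 1 - neg_ge / N_neg
  lr <- tryCatch(
    exact_score_lr(c(pos_ge, neg_ge), c(N_pos, N_neg), conf = conf),
    wbi_degenerate_error = function(e) list(lr = NA_real_, lo = NA_real_,
                                            hi = NA_real_, adjusted = TRUE))
  list(sensitivity = sens, specificity = spec,
       lr_pos = lr$lr, lr_lo = lr$lo, lr_hi = lr$hi)
}

#' Empirical ROC points
#'
#' One point per candidate threshold (each stratum lower bound plus one past
#' the top), with ties inside a stratum handled by the stratum boundaries.
#'
#' @param table a `wbi_score_table`.
#' @return Tibble `threshold`, `sensitivity`, `specificity`, `fpr`.
#' @export
roc_points <- function(table) {
  stopifnot(inherits(table, "wbi_score_table"))
  ts <- c(table$lo, table_top_score(table) + 1)
  rows <- lapply(ts, function(t) {
    ss <- sens_spec_at_threshold(table, t)
    tibble::tibble(threshold = t, sensitivity = ss$sensitivity,
                   specificity = ss$specificity, fpr = 1 - ss$specificity)
  })
  do.call(rbind, rows)
}

#' Empirical AUC with tied ordinal scores
#'
#' The probability that a random outcome-positive respondent outscores a
#' random outcome-negative one, ties counting one half (the normalized
#' Mann--Whitney statistic), computed directly from the stratum counts.
#' For a favorable outcome (where *lower* scores indicate the outcome) use
#' `direction = "low"`, which reverses the score so the AUC stays above 0.5
#' for an informative test.
#'
#' @param table a `wbi_score_table` with both classes non-empty.
#' @param direction `"high"` (default; higher score = outcome-positive
#'   direction) or `"low"`.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(table, direction = c("high", "low")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "wbi_score_table"))
  N_pos <- attr(table, "N_pos"); N_neg <- attr(table, "N_neg")
  stopifnot(N_pos > 0, N_neg > 0)
  cum_neg_below <- cumsum(c(0, table$n_neg))[seq_len(nrow(table))]
  auc <- sum(table$n_pos * (cum_neg_below + 0.5 * table$n_neg)) /
    (as.numeric(N_pos) * as.numeric(N_neg))
  if (direction == "low") auc <- 1 - auc
  auc
}

#' Smallest score above which every stratum has LR > 1
#'
#' Scans candidate thresholds (stratum lower bounds) from the bottom and
#' returns the smallest score `t` such that the exact-score likelihood ratio
#' exceeds 1 for every stratum at or above `t`, in every supplied table. This
#' identifies the score from which all higher strata indicate increased risk.
#' Because the likelihood ratios of a table average to 1 over the
#' negative-class score distribution, some stratum always has LR at or below
#' 1, so the result is strictly above the minimum score (or `NA` when the
#' top strata never rise above 1, as for a favorable outcome).
#'
#' @param tables a `wbi_score_table` or list of them (one per outcome).
#' @return The threshold score, or `NA` if no stratum set qualifies.
#' @export
select_threshold <- function(tables) {
  if (inherits(tables, "wbi_score_table")) tables <- list(tables)
  stopifnot(length(tables) > 0)
  per_table_min <- vapply(tables, function(tb) {
    lrs <- vapply(seq_len(nrow(tb)), function(i) {
      exact_score_lr(c(tb$n_pos[i], tb$n_neg[i]), score_table_totals(tb))$lr
    }, numeric(1))
    above <- rev(cumprod(rev(lrs > 1))) == 1   # all strata from i upward > 1
    if (!any(above)) return(NA_real_)
    tb$lo[which(above)[1]]
  }, numeric(1))
  if (anyNA(per_table_min)) return(NA_real_)
  max(per_table_min)
}

#' Full diagnostic stratification for one outcome
#'
#' Runs the whole per-outcome analysis: score-stratum table (optionally
#' sparse-combined), per-stratum odds ratio with Woolf interval and a
#' contingency-test p-value (Fisher when any expected cell is below 5, else
#' chi-square), exact-score likelihood ratio with Katz interval, Bayes
#' posttest probability, per-threshold sensitivity/specificity, and the
#' empirical AUC. The AUC is computed from the unbinned scores regardless of
#' `top_bin`, so the top-bin display convention does not coarsen it.
#'
#' @param scores integer score vector.
#' @param outcome logical outcome vector.
#' @param pretest pretest probability; defaults to the empirical prevalence.
#' @param top_bin open top stratum start (default 7); `NULL` to disable.
#' @param min_events if non-`NULL`, passed to [combine_sparse_strata()].
#' @param direction ROC orientation, see [empirical_auc()].
#' @return A `wbi_diagnostic` list: `table`, `strata` (tibble of per-stratum
#'   statistics), `thresholds` (tibble of sens/spec/LR+), `auc`, `pretest`,
#'   `direction`.
#' @export
diagnose_stratification <- function(scores, outcome, pretest = NULL,
                                    top_bin = 7, min_events = NULL,
                                    direction = c("high", "low")) {
  direction <- match.arg(direction)
  outcome <- as.logical(outcome)
  pretest <- pretest %||% mean(outcome)
  tab <- build_score_table(scores, outcome, top_bin = top_bin)
  if (!is.null(min_events)) {
    tab <- combine_sparse_strata(tab, min_events = min_events)
  }
  totals <- score_table_totals(tab)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    st <- c(tab$n_pos[i], tab$n_neg[i])
    or_est <- stratum_odds_ratio(st, totals)
    lr_est <- exact_score_lr(st, totals)
    p <- cont_table_test(st[1], st[2], totals[1] - st[1],
                         totals[2] - st[2])$p_value
    tibble::tibble(label = tab$label[i], n_pos = tab$n_pos[i],
                   n_neg = tab$n_neg[i], or = or_est$or, or_lo = or_est$lo,
                   or_hi = or_est$hi, p = p, lr = lr_est$lr,
                   lr_lo = lr_est$lo, lr_hi = lr_est$hi,
                   posttest = posttest_probability(pretest, lr_est$lr))
  })
  raw_tab <- build_score_table(scores, outcome, top_bin = NULL)
  out <- list(table = tab, strata = do.call(rbind, rows),
              thresholds = roc_and_lr(tab),
              auc = empirical_auc(raw_tab, direction = direction),
              pretest = pretest, direction = direction)
  class(out) <- "wbi_diagnostic"
  out
}

roc_and_lr <- function(tab) {
  ts <- c(tab$lo, table_top_score(tab) + 1)
  rows <- lapply(ts, function(t) {
    ss <- sens_spec_at_threshold(tab, t)
    tibble::tibble(threshold = t, sensitivity = ss$sensitivity,
                   specificity = ss$specificity, lr_pos = ss$lr_pos,
                   lr_lo = ss$lr_lo, lr_hi = ss$lr_hi)
  })
  do.call(rbind, rows)
}

#' @export
print.wbi_diagnostic <- function(x, ...) {
  cat(sprintf(
    "<wbi_diagnostic> %d strata, pretest %s, AUC %s (%s-score direction)\n",
    nrow(x$strata), fmt_pct(x$pretest), fmt_num(x$auc, 2), x$direction))
  print(x$strata)
  invisible(x)
}
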