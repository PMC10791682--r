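outcome_set <- c("low_qol", "high_qol", "extreme_fatigue", "burnout",
                 "suicidal_ideation", "major_error", "itl_moderate_plus")

#' Pipeline configuration
#'
#' @param threshold_mode half-SD threshold mode, `"gender_matched"` (default)
#'   or `"overall"`.
#' @param pretest_preset `"empirical"` (default for analysing a cohort:
#'   pretest = observed prevalence), `"table_footnotes"` or `"results_text"`
#'   (the published presets, used when reproducing the printed tables).
#' @param min_events minimum outcome-positive count per stratum before sparse
#'   strata are combined (default 5).
#' @param top_bin open top stratum start (default 7); `NULL` disables binning.
#' @param outcomes outcomes to analyse (default all seven).
#' @return A `wbi_config` list.
#' @export
pipeline_config <- function(threshold_mode = c("gender_matched", "overall"),
                            pretest_preset = c("empirical", "table_footnotes",
                                               "results_text"),
                            min_events = 5L, top_bin = 7L,
                            outcomes = outcome_set) {
  cfg <- list(threshold_mode = match.arg(threshold_mode),
              pretest_preset = match.arg(pretest_preset),
              min_events = min_events, top_bin = top_bin,
              outcomes = match.arg(outcomes, outcome_set,
                                   several.ok = TRUE))
  class(cfg) <- "wbi_config"
  cfg
}

#' Run the full validation pipeline on a cohort
#'
#' Executes, in order: demographics summary, composite scoring, half-SD
#' threshold derivation, outcome classification, prevalence estimation,
#' per-outcome diagnostic stratification (odds ratios, exact-score likelihood
#' ratios, posttest probabilities, sensitivity/specificity, AUC), risk
#' threshold selection across the distress outcomes, and two-group score
#' comparisons (rank-sum and Welch t) per outcome. Deterministic given the
#' cohort and configuration. The high-QOL outcome is favorable, so its ROC is
#' computed with the score reversed.
#'
#' @param cohort a `wbi_cohort`.
#' @param config a [pipeline_config()].
#' @return A `wbi_report` list: `demographics`, `scores`, `thresholds`,
#'   `outcomes`, `prevalences`, `diagnostics` (one `wbi_diagnostic` per
#'   outcome), `risk_threshold`, `group_tests`, `provenance`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "wbi_cohort"), inherits(config, "wbi_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_wbi("pipeline stage '", name, "' failed: ", conditionMessage(e),
               class = "wbi_pipeline_error")
    })
  }
  demographics <- stage("demographics", summarize_demographics(cohort))
  scores <- stage("scoring", score_cohort(cohort))
  thr_qol <- stage("thresholds", suppressWarnings(
    derive_thresholds(cohort, "qol", config$threshold_mode)))
  thr_fat <- stage("thresholds", suppressWarnings(
    derive_thresholds(cohort, "fatigue", config$threshold_mode)))
  flags <- stage("outcomes", classify_outcomes(
    cohort, thr_qol, thr_fat, mode = config$threshold_mode))
  prev <- stage("prevalences", outcome_prevalences(flags))

  pretests <- if (config$pretest_preset == "empirical") {
    stats::setNames(prev$prevalence, prev$outcome)
  } else {
    pretest_presets(config$pretest_preset)
  }

  s <- scores$scores$score
  diagnostics <- lapply(config$outcomes, function(oc) {
    stage(paste0("diagnostics:", oc), {
      pt <- pretests[[oc]]
      if (is.na(pt) || pt <= 0 || pt >= 1) {
        NULL   # degenerate outcome (all positive or negative): skip
      } else {
        diagnose_stratification(
          s, flags[[oc]], pretest = pt, top_bin = config$top_bin,
          min_events = config$min_events,
          direction = if (oc == "high_qol") "low" else "high")
      }
    })
  })
  names(diagnostics) <- config$outcomes

  distress <- setdiff(config$outcomes, "high_qol")
  risk_tables <- Filter(Negate(is.null),
                        lapply(diagnostics[distress], function(d) d$table))
  risk_threshold <- if (length(risk_tables) > 0) {
    stage("threshold_selection", select_threshold(unname(risk_tables)))
  } else NA_real_

  group_tests <- lapply(config$outcomes, function(oc) {
    f <- flags[[oc]]
    if (all(f) || !any(f)) return(NULL)
    x <- s[f]; y <- s[!f]
    list(mean_pos = mean(x), mean_neg = mean(y),
         wilcoxon = wilcoxon_rank_sum(x, y),
         t_test = if (length(x) >= 2 && length(y) >= 2)
           two_sample_t(x, y) else NULL)
  })
  names(group_tests) <- config$outcomes

  out <- list(demographics = demographics, scores = scores,
              thresholds = list(qol = thr_qol, fatigue = thr_fat),
              outcomes = flags, prevalences = prev,
              diagnostics = diagnostics, risk_threshold = risk_threshold,
              group_tests = group_tests,
              provenance = list(
                n = nrow(cohort), label = attr(cohort, "label"),
                config = unclass(config),
                package_version = as.character(
                  utils::packageVersion("wbiscreen"))))
  class(out) <- "wbi_report"
  out
}

#' @export
print.wbi_report <- function(x, ...) {
  cat(sprintf("<wbi_report> n = %d; mean score %s (SD %s); risk threshold >= %s\n",
              x$provenance$n, fmt_num(x$scores$mean, 1),
              fmt_num(x$scores$sd, 1), format(x$risk_threshold)))
  cat("outcomes analysed: ",
      paste(names(Filter(Negate(is.null), x$diagnostics)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Byte-identical output for identical cohort and configuration (no
#' timestamps). Numeric values are written unrounded.
#'
#' @param report a `wbi_report`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "wbi_report"))
  strip <- function(x) {
    if (inherits(x, "wbi_test")) return(unclass(x))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  js <- jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf("%s (%s, %s)", fmt_num(est, digits), fmt_num(lo, digits),
          fmt_num(hi, digits))
}

#' Render a report block as a display table or figure
#'
#' Mirrors the published table layouts with half-up display rounding; every
#' numeric cell is carried unrounded alongside its display string.
#'
#' * `"t1"`: demographics counts table.
#' * `"t2"`: per-stratum odds ratios for a pair of outcomes (default the QOL
#'   pair).
#' * `"t3"`: per-stratum likelihood ratios and posttest probabilities for the
#'   QOL and distress outcomes.
#' * `"t4"`: the same for the professional-consequence outcomes.
#' * `"fig1"`: score-frequency bar chart (a ggplot object).
#'
#' @param report a `wbi_report`.
#' @param which one of `"t1"`, `"t2"`, `"t3"`, `"t4"`, `"fig1"`.
#' @return A tibble (tables) or ggplot object (`"fig1"`).
#' @export
render_table <- function(report, which = c("t1", "t2", "t3", "t4", "fig1")) {
  which <- match.arg(which)
  stopifnot(inherits(report, "wbi_report"))
  if (which == "t1") {
    d <- report$demographics
    d$display <- sprintf("%d (%s%%)", d$n, fmt_num(d$pct, 1))
    return(d)
  }
  if (which == "fig1") {
    dist <- report$scores$distribution
    return(
      ggplot2::ggplot(dist, ggplot2::aes(x = factor(score), y = n)) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::labs(x = "WBI score", y = "Number of respondents",
                      title = "Composite score distribution") +
        ggplot2::theme_minimal())
  }
  ocs <- switch(which,
                t2 = c("low_qol", "high_qol"),
                t3 = c("low_qol", "high_qol", "extreme_fatigue", "burnout",
                       "suicidal_ideation"),
                t4 = c("major_error", "itl_moderate_plus"))
  ocs <- intersect(ocs, names(Filter(Negate(is.null), report$diagnostics)))
  if (length(ocs) == 0) {
    stop_wbi("report contains no diagnostics for table '", which, "'",
             class = "wbi_report_error")
  }
  rows <- lapply(ocs, function(oc) {
    st <- report$diagnostics[[oc]]$strata
    if (which == "t2") {
      tibble::tibble(outcome = oc, label = st$label, n_pos = st$n_pos,
                     n_neg = st$n_neg, or = st$or, or_lo = st$or_lo,
                     or_hi = st$or_hi, p = st$p,
                     display = sprintf("%s; p = %s", fmt_ci(st$or, st$or_lo,
                                                            st$or_hi),
                                       fmt_num(st$p, 3)))
    } else {
      tibble::tibble(outcome = oc, label = st$label, lr = st$lr,
                     lr_lo = st$lr_lo, lr_hi = st$lr_hi,
                     posttest = st$posttest,
                     display = sprintf("%s; posttest %s",
                                       fmt_ci(st$lr, st$lr_lo, st$lr_hi),
                                       fmt_pct(st$posttest)))
    }
  })
  do.call(rbind, rows)
}

#' Reproduce the published stratification tables from the embedded fixtures
#'
#' Recomputes the odds-ratio table and the likelihood-ratio/posttest tables
#' from the embedded printed counts ([table2_fixture()]) and printed
#' likelihood ratios ([printed_lr_fixture()]), using the footnote pretest
#' preset. Runs with no external input.
#'
#' @param which `"t2"` (odds ratios, QOL pair, from counts), `"t3"`
#'   (LR/posttest: QOL pair from counts, distress outcomes from printed LRs)
#'   or `"t4"` (professional consequences from printed LRs).
#' @return A tibble; `t2` rows carry `or`/`or_lo`/`or_hi`/`p`, LR tables
#'   carry `lr`/`posttest` (plus intervals where computed from counts).
#' @export
reproduce_tables <- function(which = c("t2", "t3", "t4")) {
  which <- match.arg(which)
  fix <- table2_fixture()
  pre <- pretest_presets("table_footnotes")
  from_counts <- function(tab, outcome) {
    totals <- score_table_totals(tab)
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      st <- c(tab$n_pos[i], tab$n_neg[i])
      or_est <- stratum_odds_ratio(st, totals)
      lr_est <- exact_score_lr(st, totals)
      p <- cont_table_test(st[1], st[2], totals[1] - st[1],
                           totals[2] - st[2])$p_value
      tibble::tibble(outcome = outcome, label = tab$label[i],
                     n_pos = tab$n_pos[i], n_neg = tab$n_neg[i],
                     or = or_est$or, or_lo = or_est$lo, or_hi = or_est$hi,
                     p = p, lr = lr_est$lr, lr_lo = lr_est$lo,
                     lr_hi = lr_est$hi,
                     posttest = posttest_probability(pre[[outcome]],
                                                     lr_est$lr))
    })
    do.call(rbind, rows)
  }
  if (which == "t2") {
    tb <- rbind(from_counts(fix$low_qol, "low_qol"),
                from_counts(fix$high_qol, "high_qol"))
    tb$display <- fmt_ci(tb$or, tb$or_lo, tb$or_hi)
    return(tb)
  }
  printed <- printed_lr_fixture()
  ocs <- if (which == "t3") {
    c("extreme_fatigue", "burnout", "suicidal_ideation")
  } else {
    c("major_error", "itl_moderate_plus")
  }
  from_printed <- do.call(rbind, lapply(ocs, function(oc) {
    p <- printed[printed$outcome == oc, ]
    tibble::tibble(outcome = oc, label = p$label, lr = p$lr,
                   posttest = posttest_probability(pre[[oc]], p$lr))
  }))
  if (which == "t4") {
    from_printed$display <- fmt_pct(from_printed$posttest)
    return(from_printed)
  }
  qol <- rbind(from_counts(fix$low_qol, "low_qol"),
               from_counts(fix$high_qol, "high_qol"))
  qol <- qol[, c("outcome", "label", "lr", "posttest")]
  out <- rbind(qol, from_printed)
  out$display <- fmt_pct(out$posttest)
  out
}
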