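#' Likert contribution map for the two favorable-worded items
#'
#' The meaning-in-work and work-life-integration items are worded favorably,
#' so agreement is protective: agree/strongly agree contribute -1, neutral 0,
#' disagree/strongly disagree +1 to the composite score. The map is exposed so
#' an alternative item-to-contribution table can be dropped in.
#'
#' @return Named integer vector over the five Likert levels.
#' @export
wbi_likert_map <- function() {
  c("strongly agree" = -1L, "agree" = -1L, "neutral" = 0L,
    "disagree" = 1L, "strongly disagree" = 1L)
}

#' Score the 9-item Well-Being Index
#'
#' The composite is the count of "yes" answers over the seven dichotomous
#' distress items plus the contributions of the two favorable-worded Likert
#' items (-1/0/+1 each, see [wbi_likert_map()]), giving an integer in
#' -2..9 where higher means more distress.
#'
#' This is the published expanded-index additive rule; the instrument's own
#' scoring table is distributed with the licensed survey, so the item map is
#' configurable via `likert_map`.
#'
#' @param binary character/factor vector of length 7, values `"yes"`/`"no"`.
#' @param meaning,wli single 5-level Likert responses (levels of
#'   `wbi_levels$likert5`).
#' @param likert_map named contribution map, by default [wbi_likert_map()].
#' @return Integer score in \[-2, 9\].
#' @export
#' @examples
#' score_wbi(rep("no", 7), "strongly agree", "strongly agree")  # -2
#' score_wbi(rep("yes", 7), "strongly disagree", "strongly disagree") # 9
score_wbi <- function(binary, meaning, wli, likert_map = wbi_likert_map()) {
  binary <- tolower(trimws(as.character(binary)))
  meaning <- tolower(trimws(as.character(meaning)))
  wli <- tolower(trimws(as.character(wli)))
  if (length(binary) != 7) {
    stop_wbi("exactly 7 dichotomous item responses required",
             class = "wbi_scoring_error")
  }
  items <- c(binary, meaning, wli)
  if (anyNA(items) || any(items == "")) {
    stop_wbi("all 9 items must be answered; no imputation is performed",
             class = "wbi_scoring_error")
  }
  if (!all(binary %in% wbi_levels$yes_no)) {
    stop_wbi("dichotomous items must be 'yes' or 'no'",
             class = "wbi_scoring_error")
  }
  if (!all(c(meaning, wli) %in% names(likert_map))) {
    stop_wbi("Likert responses must be one of: ",
             paste(names(likert_map), collapse = ", "),
             class = "wbi_scoring_error")
  }
  sum(binary == "yes") + likert_map[[meaning]] + likert_map[[wli]]
}

#' Score every respondent in a cohort
#'
#' @param cohort a `wbi_cohort`.
#' @param likert_map contribution map for the favorable-worded items.
#' @return A list of class `wbi_scores`: `scores` (tibble `id`, `score`),
#'   `distribution` (tibble `score`, `n`, counts summing to the cohort size),
#'   `mean` and `sd` of the scores.
#' @export
score_cohort <- function(cohort, likert_map = wbi_likert_map()) {
  stopifnot(inherits(cohort, "wbi_cohort"), nrow(cohort) > 0)
  ym <- vapply(wbi_binary_items, function(cl) cohort[[cl]] == "yes",
               logical(nrow(cohort)))
  if (is.null(dim(ym))) ym <- matrix(ym, nrow = 1)   # single respondent
  yes <- rowSums(ym)
  s <- as.integer(yes) +
    likert_map[as.character(cohort$wbi_meaning)] +
    likert_map[as.character(cohort$wbi_wli)]
  s <- as.integer(unname(s))
  if (anyNA(s)) {
    stop_wbi("scoring failed for respondent(s): ",
             paste(cohort$id[is.na(s)], collapse = ", "),
             class = "wbi_scoring_error")
  }
  dist <- table(factor(s, levels = min(s):max(s)))
  out <- list(
    scores = tibble::tibble(id = cohort$id, score = s),
    distribution = tibble::tibble(score = as.integer(names(dist)),
                                  n = as.integer(dist)),
    mean = mean(s),
    sd = stats::sd(s)
  )
  class(out) <- "wbi_scores"
  out
}

#' @export
print.wbi_scores <- function(x, ...) {
  cat(sprintf("<wbi_scores> n = %d, mean = %s, sd = %s\n",
              nrow(x$scores), fmt_num(x$mean, 2),
              fmt_num(x$sd, 2)))
  invisible(x)
}
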