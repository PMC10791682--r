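#' Half-SD cutoffs from a mean and SD
#'
#' The clinically meaningful effect size used for the linear-analogue scales:
#' low status is half a standard deviation or more below the group mean
#' (inclusive), high status strictly more than half an SD above it.
#'
#' @param mean,sd group mean and standard deviation (`sd >= 0`).
#' @return Named numeric vector `c(low_cutoff =, high_cutoff =)`.
#' @export
#' @examples
#' half_sd_cutoffs(7.1, 1.6) # low 6.3, high 7.9
half_sd_cutoffs <- function(mean, sd) {
  stopifnot(sd >= 0)
  c(low_cutoff = mean - 0.5 * sd, high_cutoff = mean + 0.5 * sd)
}

#' Derive half-SD thresholds for a linear-analogue scale
#'
#' Computes per-gender (or whole-cohort) mean and sample SD of the 0--10 QOL
#' or fatigue scale and the half-SD cutoffs. Respondents with missing gender
#' are evaluated against the whole-cohort thresholds, so an `"overall"` row is
#' always included. A subgroup with zero SD gets a degenerate-threshold
#' warning and its members are never classified low or high.
#'
#' @param cohort a `wbi_cohort`.
#' @param scale `"qol"` or `"fatigue"`.
#' @param mode `"gender_matched"` (default, per-gender moments) or
#'   `"overall"` (whole-cohort moments applied to everyone).
#' @return A `wbi_thresholds` tibble: `group`, `scale`, `n`, `mean`, `sd`,
#'   `low_cutoff`, `high_cutoff`, `degenerate`.
#' @export
derive_thresholds <- function(cohort, scale = c("qol", "fatigue"),
                              mode = c("gender_matched", "overall")) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "wbi_cohort"))
  v <- as.numeric(cohort[[scale]])

  one <- function(group, x) {
    m <- mean(x); s <- if (length(x) > 1) stats::sd(x) else 0
    cut <- half_sd_cutoffs(m, s)
    tibble::tibble(group = group, scale = scale, n = length(x), mean = m,
                   sd = s, low_cutoff = cut[["low_cutoff"]],
                   high_cutoff = cut[["high_cutoff"]], degenerate = s == 0)
  }

  rows <- list(one("overall", v))
  if (mode == "gender_matched") {
    for (g in wbi_levels$gender) {
      x <- v[!is.na(cohort$gender) & cohort$gender == g]
      if (length(x) < 2) {
        stop_wbi("need at least 2 respondents of gender '", g,
                 "' for gender-matched thresholds", class = "wbi_threshold_error")
      }
      rows <- c(rows, list(one(g, x)))
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$degenerate)) {
    warning("degenerate thresholds (SD = 0) for group(s): ",
            paste(out$group[out$degenerate], collapse = ", "),
            "; members will not be classified low or high")
  }
  class(out) <- c("wbi_thresholds", class(out))
  out
}

threshold_row <- function(thresholds, gender) {
  grp <- ifelse(is.na(gender), "overall", as.character(gender))
  grp[!grp %in% thresholds$group] <- "overall"
  idx <- match(grp, thresholds$group)
  thresholds[idx, , drop = FALSE]
}

#' Derive the binary reference-standard outcomes
#'
#' Applies the half-SD rules and item rules to every respondent:
#' * `low_qol`: QOL at or below the low cutoff (the boundary is inclusive);
#'   `high_qol`: QOL strictly above the high cutoff. Never both.
#' * `extreme_fatigue`: fatigue at or below its low cutoff (the scale's high
#'   end is favorable).
#' * `high_ee` / `high_dp`: symptom frequency weekly or more often;
#'   `burnout` is their union.
#' * `suicidal_ideation`, `major_error`: item pass-through.
#' * `itl_moderate_plus`: intent to leave moderate, likely or definite.
#'
#' @param cohort a `wbi_cohort`.
#' @param qol_thresholds,fatigue_thresholds `wbi_thresholds` tables; derived
#'   from `cohort` with `mode` when omitted.
#' @param mode threshold mode passed to [derive_thresholds()].
#' @return A `wbi_outcomes` tibble: `id` plus one logical column per outcome.
#' @export
classify_outcomes <- function(cohort, qol_thresholds = NULL,
                              fatigue_thresholds = NULL,
                              mode = c("gender_matched", "overall")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "wbi_cohort"))
  if (is.null(qol_thresholds)) {
    qol_thresholds <- suppressWarnings(derive_thresholds(cohort, "qol", mode))
  }
  if (is.null(fatigue_thresholds)) {
    fatigue_thresholds <- suppressWarnings(
      derive_thresholds(cohort, "fatigue", mode))
  }
  gender <- if (mode == "overall") rep(NA_character_, nrow(cohort)) else
    cohort$gender
  qt <- threshold_row(qol_thresholds, gender)
  ft <- threshold_row(fatigue_thresholds, gender)

  weekly_plus <- wbi_levels$freq7[5:7]
  out <- tibble::tibble(
    id = cohort$id,
    low_qol  = !qt$degenerate & cohort$qol <= qt$low_cutoff,
    high_qol = !qt$degenerate & cohort$qol > qt$high_cutoff,
    extreme_fatigue = !ft$degenerate & cohort$fatigue <= ft$low_cutoff,
    high_ee = cohort$ee_freq %in% weekly_plus,
    high_dp = cohort$dp_freq %in% weekly_plus,
    suicidal_ideation = cohort$suicidal_ideation == "yes",
    major_error = cohort$major_error == "yes",
    itl_moderate_plus = cohort$intent_to_leave %in%
      c("moderate", "likely", "definite")
  )
  out$burnout <- out$high_ee | out$high_dp
  out <- out[, c("id", "low_qol", "high_qol", "extreme_fatigue", "high_ee",
                 "high_dp", "burnout", "suicidal_ideation", "major_error",
                 "itl_moderate_plus")]
  class(out) <- c("wbi_outcomes", class(out))
  out
}

#' Outcome prevalences
#'
#' Proportion of the cohort positive on each derived outcome; these are the
#' empirical pretest probabilities for the posttest-probability computation.
#'
#' @param flags a `wbi_outcomes` tibble from [classify_outcomes()].
#' @return Tibble `outcome`, `n_pos`, `n`, `prevalence` (proportion in 0--1).
#' @export
outcome_prevalences <- function(flags) {
  stopifnot(inherits(flags, "wbi_outcomes"))
  cols <- setdiff(names(flags), "id")
  tibble::tibble(
    outcome = cols,
    n_pos = vapply(cols, function(cl) sum(flags[[cl]]), integer(1),
                   USE.NAMES = FALSE),
    n = nrow(flags),
    prevalence = vapply(cols, function(cl) mean(flags[[cl]]), numeric(1),
                        USE.NAMES = FALSE)
  )
}

#' Pretest probability presets
#'
#' Two published prevalence sets are available for reproducing the printed
#' stratification tables: the table-footnote values used for the posttest
#' columns, and the slightly different Results-text values (the high-QOL,
#' fatigue, error and intent-to-leave figures differ between the two places
#' in the source report; both are shipped verbatim).
#'
#' @param preset `"table_footnotes"` (default) or `"results_text"`.
#' @return Named numeric vector of pretest probabilities (0--1 scale) for
#'   `low_qol`, `high_qol`, `extreme_fatigue`, `burnout`, `suicidal_ideation`,
#'   `major_error`, `itl_moderate_plus`.
#' @export
pretest_presets <- function(preset = c("table_footnotes", "results_text")) {
  preset <- match.arg(preset)
  switch(preset,
    table_footnotes = c(
      low_qol = 0.273, high_qol = 0.451, extreme_fatigue = 0.332,
      burnout = 0.441, suicidal_ideation = 0.062, major_error = 0.201,
      itl_moderate_plus = 0.235),
    results_text = c(
      low_qol = 0.273, high_qol = 0.461, extreme_fatigue = 0.400,
      burnout = 0.441, suicidal_ideation = 0.062, major_error = 0.208,
      itl_moderate_plus = 0.234)
  )
}
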