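# expected value of plogis(a + b*z) over z ~ N(0,1)
logistic_normal_mean <- function(a, b) {
  stats::integrate(function(z) stats::plogis(a + b * z) * stats::dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# intercept a such that E[plogis(a + b z)] equals the target marginal
latent_intercept <- function(target, loading) {
  stopifnot(target > 0, target < 1, loading >= 0)
  if (loading == 0) return(stats::qlogis(target))
  stats::uniroot(function(a) logistic_normal_mean(a, loading) - target,
                 interval = c(-40, 40), tol = 1e-10)$root
}

# cutpoints c_k such that E[plogis(c_k - b z)] equals each cumulative target
latent_cutpoints <- function(cum_targets, loading) {
  stopifnot(all(diff(cum_targets) > 0), all(cum_targets > 0),
            all(cum_targets < 1), loading >= 0)
  vapply(cum_targets, function(p) latent_intercept(p, loading), numeric(1))
}

#' Synthetic cohort generator parameters
#'
#' Configuration for the single-factor latent-trait generator: one standard
#' normal distress value `z` per respondent drives every distress indicator.
#' Each dichotomous WBI item is Bernoulli with probability
#' `plogis(intercept + loading * z)`; Likert, symptom-frequency and
#' intent-to-leave items follow ordinal-logistic models on `z`; the 0--10 QOL
#' and fatigue scales are `clamp(round(base + slope * z + noise), 0, 10)`;
#' suicidal ideation and major error are Bernoulli on logistic links.
#' Demographics are drawn independently of `z`.
#'
#' Parameters are specified as *marginal targets* (the prevalence each
#' indicator should have in a large cohort) plus factor loadings; intercepts
#' and cutpoints are derived by integrating the logistic link over the latent
#' normal, so changing a loading (including to 0 for a null generator) keeps
#' the marginals fixed. The shipped defaults target the reference survey's
#' marginals: mean composite score about 2.3 (SD 2.5), low QOL 27.3%,
#' high QOL ~45%, extreme fatigue ~33%, burnout 44.1% (high emotional
#' exhaustion 37.5%, high depersonalization 26.5%), suicidal ideation 6.2%,
#' recent major error ~20.5%, moderate-plus intent to leave 23.5%.
#'
#' @param n cohort size (default 597, the reference sample size).
#' @param seed integer seed used by [generate_cohort()].
#' @param gender_split probability of `"woman"` (default 0.461).
#' @param gender_missing probability gender is missing (default 1/597).
#' @param item_marginals,item_loadings length-7 endorsement probabilities and
#'   non-negative loadings for the dichotomous items.
#' @param likert_marginals cumulative probabilities (4 values) of the five
#'   Likert levels for the favorable-worded items, agreement end first.
#' @param meaning_loading,wli_loading loadings of the two Likert items.
#' @param qol_anchor,fatigue_anchor named vectors `base`, `slope` (<= 0),
#'   `noise_sd` for the linear-analogue scales.
#' @param ee_marginals,dp_marginals cumulative probabilities (6 values) over
#'   the 7 frequency levels, `never` end first.
#' @param ee_loading,dp_loading frequency-item loadings.
#' @param si_marginal,si_loading,error_marginal,error_loading Bernoulli
#'   outcome targets and loadings.
#' @param itl_marginals cumulative probabilities (4 values) over the 5
#'   intent-to-leave levels, `none` end first.
#' @param itl_loading intent-to-leave loading.
#' @param demographics list of category probability vectors for `age_band`,
#'   `years_in_practice`, `setting`, `specialty` (defaults follow the
#'   reference sample's demographic table).
#' @return A validated `wbi_cohort_params` list, including the derived
#'   `item_intercepts`, `*_cutpoints`, `si_intercept` and `error_intercept`.
#' @export
cohort_params <- function(
    n = 597, seed = 1L,
    gender_split = 0.461, gender_missing = 1 / 597,
    item_marginals = c(0.55, 0.50, 0.45, 0.42, 0.38, 0.32, 0.28),
    item_loadings = rep(0.88, 7),
    likert_marginals = c(0.25, 0.55, 0.75, 0.90),
    meaning_loading = 1.0, wli_loading = 1.0,
    qol_anchor = c(base = 8.4, slope = -1.12, noise_sd = 0.9),
    fatigue_anchor = c(base = 7.2, slope = -1.0, noise_sd = 1.5),
    ee_marginals = cumsum(c(0.12, 0.18, 0.15, 0.175, 0.15, 0.125)),
    ee_loading = 2.6,
    dp_marginals = cumsum(c(0.20, 0.22, 0.17, 0.145, 0.11, 0.085)),
    dp_loading = 2.4,
    si_marginal = 0.062, si_loading = 1.0,
    error_marginal = 0.205, error_loading = 0.55,
    itl_marginals = c(0.35, 0.765, 0.88, 0.95),
    itl_loading = 1.1,
    demographics = list(
      age_band = c(205, 181, 109, 70, 32) / 597,
      years_in_practice = c(182, 193, 104, 118) / 597,
      setting = c(453, 50, 34, 58, 2) / 597,
      specialty = c(581, 16) / 597)) {
  stopifnot(n >= 1, length(item_marginals) == 7, length(item_loadings) == 7,
            all(item_loadings >= 0), all(item_marginals > 0),
            all(item_marginals < 1),
            gender_split >= 0, gender_split <= 1,
            qol_anchor[["slope"]] <= 0, fatigue_anchor[["slope"]] <= 0,
            qol_anchor[["noise_sd"]] >= 0, fatigue_anchor[["noise_sd"]] >= 0,
            si_loading >= 0, error_loading >= 0, ee_loading >= 0,
            dp_loading >= 0, itl_loading >= 0,
            length(likert_marginals) == 4, length(ee_marginals) == 6,
            length(dp_marginals) == 6, length(itl_marginals) == 4)
  for (nm in c("age_band", "years_in_practice", "setting", "specialty")) {
    p <- demographics[[nm]]
    if (is.null(p) || length(p) != length(wbi_levels[[nm]]) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop_wbi("demographics$", nm, " must be one probability per '", nm,
               "' category, summing to 1", class = "wbi_param_error")
    }
  }
  params <- list(
    n = as.integer(n), seed = as.integer(seed),
    gender_split = gender_split, gender_missing = gender_missing,
    item_marginals = item_marginals, item_loadings = item_loadings,
    item_intercepts = mapply(latent_intercept, item_marginals, item_loadings),
    likert_marginals = likert_marginals,
    meaning_loading = meaning_loading, wli_loading = wli_loading,
    meaning_cutpoints = latent_cutpoints(likert_marginals, meaning_loading),
    wli_cutpoints = latent_cutpoints(likert_marginals, wli_loading),
    qol_anchor = qol_anchor, fatigue_anchor = fatigue_anchor,
    ee_marginals = ee_marginals, ee_loading = ee_loading,
    ee_cutpoints = latent_cutpoints(ee_marginals, ee_loading),
    dp_marginals = dp_marginals, dp_loading = dp_loading,
    dp_cutpoints = latent_cutpoints(dp_marginals, dp_loading),
    si_marginal = si_marginal, si_loading = si_loading,
    si_intercept = latent_intercept(si_marginal, si_loading),
    error_marginal = error_marginal, error_loading = error_loading,
    error_intercept = latent_intercept(error_marginal, error_loading),
    itl_marginals = itl_marginals, itl_loading = itl_loading,
    itl_cutpoints = latent_cutpoints(itl_marginals, itl_loading),
    demographics = demographics)
  class(params) <- "wbi_cohort_params"
  params
}

#' Null-model generator parameters
#'
#' Convenience wrapper for [cohort_params()] with every latent-trait loading
#' (and both linear-analogue slopes) set to zero: all indicators become
#' mutually independent with the same marginals, so the composite score
#' carries no information about any outcome. Under this null the per-score
#' likelihood ratios converge to 1 and every AUC to 0.5 as `n` grows.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param ... further overrides passed to [cohort_params()].
#' @return A `wbi_cohort_params` object.
#' @export
null_cohort_params <- function(n = 597, seed = 1L, ...) {
  cohort_params(
    n = n, seed = seed,
    item_loadings = rep(0, 7), meaning_loading = 0, wli_loading = 0,
    qol_anchor = c(base = 8.4, slope = 0, noise_sd = 0.9),
    fatigue_anchor = c(base = 7.2, slope = 0, noise_sd = 1.5),
    ee_loading = 0, dp_loading = 0, si_loading = 0, error_loading = 0,
    itl_loading = 0, ...)
}

draw_categorical <- function(u, probs, levels) {
  cum <- cumsum(probs)
  levels[1 + findInterval(u, cum[-length(cum)])]
}

draw_ordinal <- function(u, z, cutpoints, loading, levels) {
  cum <- stats::plogis(outer(-loading * z, cutpoints, `+`))
  levels[1 + rowSums(u > cum)]
}

#' Generate a synthetic survey cohort
#'
#' Draws `params$n` respondents under the latent-trait model described in
#' [cohort_params()]. Generation is fully reproducible from the seed; random
#' draws are consumed vectorized field-by-field in the respondent-record
#' field order (latent trait, gender, demographics, WBI items, Likert items,
#' QOL, fatigue, frequency items, outcomes).
#'
#' @param params a `wbi_cohort_params` object.
#' @param seed optional seed overriding `params$seed`.
#' @param label cohort label.
#' @return A `wbi_generated_cohort` list: `cohort` (a `wbi_cohort`), `latent`
#'   (the hidden per-respondent distress values, kept only for recovery
#'   testing, never consumed by analysis stages) and `params`.
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL,
                            label = "synthetic") {
  stopifnot(inherits(params, "wbi_cohort_params"))
  set.seed(seed %||% params$seed)
  n <- params$n
  z <- stats::rnorm(n)

  gender <- draw_categorical(stats::runif(n),
                             c(1 - params$gender_split, params$gender_split),
                             wbi_levels$gender)
  gender[stats::runif(n) < params$gender_missing] <- NA_character_

  dg <- params$demographics
  age <- draw_categorical(stats::runif(n), dg$age_band, wbi_levels$age_band)
  yrs <- draw_categorical(stats::runif(n), dg$years_in_practice,
                          wbi_levels$years_in_practice)
  setting <- draw_categorical(stats::runif(n), dg$setting, wbi_levels$setting)
  spec <- draw_categorical(stats::runif(n), dg$specialty,
                           wbi_levels$specialty)

  items <- lapply(1:7, function(j) {
    p <- stats::plogis(params$item_intercepts[j] + params$item_loadings[j] * z)
    ifelse(stats::runif(n) < p, "yes", "no")
  })
  names(items) <- wbi_binary_items

  meaning <- draw_ordinal(stats::runif(n), z, params$meaning_cutpoints,
                          params$meaning_loading, wbi_levels$likert5)
  wli <- draw_ordinal(stats::runif(n), z, params$wli_cutpoints,
                      params$wli_loading, wbi_levels$likert5)

  las <- function(anchor) {
    x <- anchor[["base"]] + anchor[["slope"]] * z +
      stats::rnorm(n, 0, anchor[["noise_sd"]])
    pmin(10L, pmax(0L, as.integer(round(x))))
  }
  qol <- las(params$qol_anchor)
  fatigue <- las(params$fatigue_anchor)

  ee <- draw_ordinal(stats::runif(n), z, params$ee_cutpoints,
                     params$ee_loading, wbi_levels$freq7)
  dp <- draw_ordinal(stats::runif(n), z, params$dp_cutpoints,
                     params$dp_loading, wbi_levels$freq7)
  si <- ifelse(stats::runif(n) <
                 stats::plogis(params$si_intercept + params$si_loading * z),
               "yes", "no")
  err <- ifelse(stats::runif(n) <
                  stats::plogis(params$error_intercept +
                                  params$error_loading * z),
                "yes", "no")
  itl <- draw_ordinal(stats::runif(n), z, params$itl_cutpoints,
                      params$itl_loading, wbi_levels$intent_to_leave)

  df <- data.frame(
    id = sprintf("R%05d", seq_len(n)), gender = gender, age_band = age,
    years_in_practice = yrs, setting = setting, specialty = spec,
    items, wbi_meaning = meaning, wbi_wli = wli, qol = qol, fatigue = fatigue,
    ee_freq = ee, dp_freq = dp, suicidal_ideation = si, major_error = err,
    intent_to_leave = itl, check.names = FALSE)
  out <- list(cohort = new_cohort(df, label = label), latent = z,
              params = params)
  class(out) <- "wbi_generated_cohort"
  out
}

#' @export
print.wbi_generated_cohort <- function(x, ...) {
  cat(sprintf("<wbi_generated_cohort> n = %d, seed = %d\n",
              x$params$n, x$params$seed))
  invisible(x)
}

#' Embedded score-stratum fixture for the QOL outcomes
#'
#' The printed per-score counts of the reference survey's low- and high-QOL
#' cross-tabulations (597 respondents; 163/434 low-QOL split, 275/322
#' high-QOL split across ten strata, top stratum open at 7), plus the
#' per-score cohort totals. This is the ground truth for the printed-value
#' reproduction tests and needs no external input.
#'
#' @return List `low_qol`, `high_qol` (both `wbi_score_table`) and
#'   `score_totals` (tibble `score`, `n`).
#' @export
table2_fixture <- function() {
  lo <- c(-2:6, 7)
  hi <- c(-2:6, Inf)
  low <- new_score_table(lo, hi,
    n_pos = c(1, 4, 4, 10, 14, 27, 25, 31, 28, 19),
    n_neg = c(47, 49, 57, 61, 67, 58, 45, 32, 10, 8))
  high <- new_score_table(lo, hi,
    n_pos = c(39, 43, 45, 38, 43, 30, 18, 15, 3, 1),
    n_neg = c(9, 10, 16, 33, 38, 55, 52, 48, 35, 26))
  list(low_qol = low, high_qol = high,
       score_totals = tibble::tibble(
         score = c(-2:6, 7),
         n = c(48, 53, 61, 71, 81, 85, 70, 63, 38, 27)))
}

#' Embedded printed exact-score likelihood ratios
#'
#' The published per-stratum likelihood-ratio point estimates for all seven
#' outcomes (the suicidal-ideation strata below score 2 are combined, as
#' published). Together with the footnote pretest probabilities
#' ([pretest_presets()]), these are the inputs for reproducing the posttest
#' probability columns of the published stratification tables for outcomes
#' whose raw counts were not printed.
#'
#' @return Tibble `outcome`, `label`, `lr`.
#' @export
printed_lr_fixture <- function() {
  full_labels <- c(as.character(-2:6), ">=7")
  si_labels <- c("-2 to 1", as.character(2:6), ">=7")
  tibble::tibble(
    outcome = c(rep("low_qol", 10), rep("high_qol", 10),
                rep("extreme_fatigue", 10), rep("burnout", 10),
                rep("suicidal_ideation", 7), rep("major_error", 10),
                rep("itl_moderate_plus", 10)),
    label = c(rep(full_labels, 4), si_labels, rep(full_labels, 2)),
    lr = c(
      0.06, 0.22, 0.19, 0.44, 0.56, 1.24, 1.48, 2.58, 7.46, 6.32,   # low QOL
      5.07, 5.03, 3.29, 1.35, 1.32, 0.64, 0.41, 0.37, 0.10, 0.05,   # high QOL
      0.23, 0.16, 0.35, 0.59, 1.12, 1.22, 1.19, 2.22, 2.77, 8.87,   # fatigue
      0.03, 0.10, 0.14, 0.43, 0.83, 1.36, 3.17, 5.40, 6.77, 15.87,  # burnout
      0.13, 1.00, 1.15, 1.95, 1.89, 0.84, 5.30,                     # SI
      0.25, 0.40, 0.27, 0.94, 0.94, 1.33, 1.22, 1.53, 2.77, 1.91,   # error
      0.14, 0.13, 0.29, 0.73, 0.93, 0.76, 1.70, 2.29, 3.26, 4.08))  # ITL
}
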