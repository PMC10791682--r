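#' Closed response sets for the survey fields
#'
#' Canonical category labels for every categorical field of a respondent
#' record: demographics, the seven dichotomous WBI items, the two
#' favorable-worded Likert items, the two single-item burnout-domain frequency
#' items, and the outcome items. Values read from CSV are matched against
#' these labels case-insensitively after whitespace trimming.
#'
#' @format A named list of character vectors.
#' @export
wbi_levels <- list(
  gender            = c("man", "woman"),
  age_band          = c("<35", "35-44", "45-54", "55-64", "65+"),
  years_in_practice = c("<5", "5-14", "15-24", "25+"),
  setting           = c("DSO-associate", "group-associate", "group-partner",
                        "self-owned", "other"),
  specialty         = c("general", "other"),
  yes_no            = c("no", "yes"),
  likert5           = c("strongly agree", "agree", "neutral", "disagree",
                        "strongly disagree"),
  freq7             = c("never", "a few times a year or less",
                        "once a month or less", "a few times a month",
                        "once a week", "a few times a week", "every day"),
  intent_to_leave   = c("none", "slight", "moderate", "likely", "definite")
)

# 7 dichotomous distress item column names (burnout, depression, stress,
# mental/physical QOL, fatigue, worry domains of the instrument)
wbi_binary_items <- paste0("wbi", 1:7)

cohort_columns <- c(
  "id", "gender", "age_band", "years_in_practice", "setting", "specialty",
  wbi_binary_items, "wbi_meaning", "wbi_wli", "qol", "fatigue",
  "ee_freq", "dp_freq", "suicidal_ideation", "major_error", "intent_to_leave"
)

col_spec <- function() {
  list(
    gender = "gender", age_band = "age_band",
    years_in_practice = "years_in_practice", setting = "setting",
    specialty = "specialty",
    wbi1 = "yes_no", wbi2 = "yes_no", wbi3 = "yes_no", wbi4 = "yes_no",
    wbi5 = "yes_no", wbi6 = "yes_no", wbi7 = "yes_no",
    wbi_meaning = "likert5", wbi_wli = "likert5",
    ee_freq = "freq7", dp_freq = "freq7",
    suicidal_ideation = "yes_no", major_error = "yes_no",
    intent_to_leave = "intent_to_leave"
  )
}

#' Construct and validate a respondent cohort
#'
#' A cohort is a tibble with one row per respondent and the fixed column set
#' (`id`, demographics, `wbi1`..`wbi7`, `wbi_meaning`, `wbi_wli`, `qol`,
#' `fatigue`, `ee_freq`, `dp_freq`, `suicidal_ideation`, `major_error`,
#' `intent_to_leave`). Categorical columns become factors over the closed sets
#' in [wbi_levels] (`wbi_meaning`/`wbi_wli`, `ee_freq`/`dp_freq` and
#' `intent_to_leave` ordered); `qol` and `fatigue` are integers in 0--10.
#' Only `gender` may be missing.
#'
#' @param data data frame with the columns above (character or factor
#'   categoricals accepted; matching is case-insensitive after trimming).
#' @param label optional cohort label, kept as an attribute.
#' @return A validated `wbi_cohort` tibble.
#' @export
new_cohort <- function(data, label = "") {
  miss <- setdiff(cohort_columns, names(data))
  if (length(miss) > 0) {
    stop_wbi("missing required column(s): ", paste(miss, collapse = ", "),
             class = "wbi_schema_error")
  }
  data <- as.data.frame(data)[cohort_columns]
  n <- nrow(data)
  problems <- character(0)

  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    problems <- c(problems, "duplicate respondent ids")
  }

  spec <- col_spec()
  ordered_cols <- c("wbi_meaning", "wbi_wli", "ee_freq", "dp_freq",
                    "intent_to_leave")
  for (col in names(spec)) {
    levs <- wbi_levels[[spec[[col]]]]
    raw <- trimws(as.character(data[[col]]))
    raw[raw == ""] <- NA_character_
    idx <- match(tolower(raw), tolower(levs))
    bad <- which(!is.na(raw) & is.na(idx))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "field '%s': invalid value(s) %s at row(s) %s", col,
        paste(unique(sQuote(raw[bad])), collapse = ", "),
        paste(utils::head(bad, 5), collapse = ", ")))
    }
    na_rows <- which(is.na(raw))
    if (col != "gender" && length(na_rows) > 0) {
      problems <- c(problems, sprintf(
        "field '%s': missing value(s) at row(s) %s (only gender may be missing)",
        col, paste(utils::head(na_rows, 5), collapse = ", ")))
    }
    data[[col]] <- factor(levs[idx], levels = levs,
                          ordered = col %in% ordered_cols)
  }

  for (col in c("qol", "fatigue")) {
    v <- suppressWarnings(as.numeric(as.character(data[[col]])))
    bad <- which(is.na(v) | v != round(v) | v < 0 | v > 10)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "field '%s': values must be integers in [0, 10]; violated at row(s) %s",
        col, paste(utils::head(bad, 5), collapse = ", ")))
    }
    data[[col]] <- as.integer(v)
  }

  if (length(problems) > 0) {
    stop_wbi("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
             class = "wbi_validation_error")
  }

  out <- tibble::as_tibble(data)
  attr(out, "label") <- as.character(label)
  class(out) <- c("wbi_cohort", class(out))
  out
}

#' @export
print.wbi_cohort <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<wbi_cohort> %d respondents%s\n", nrow(x),
              if (nzchar(lab)) paste0(" [", lab, "]") else ""))
  NextMethod()
}

#' Read a respondent cohort from CSV
#'
#' Reads a comma-separated UTF-8 file with a header row naming every cohort
#' column, validates it against the closed response sets, and returns a
#' [new_cohort()] tibble. Blank `gender` cells become missing; a blank in any
#' other field, a value outside its closed set, or `qol`/`fatigue` outside
#' 0--10 is a validation error naming the row and field.
#'
#' @param path path to the CSV file.
#' @param dialect list of CSV dialect options passed through to
#'   [utils::read.csv()] (e.g. `sep`); defaults to comma-separated.
#' @param label cohort label; defaults to the file name.
#' @return A `wbi_cohort` tibble.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(path, dialect = list(), label = basename(path)) {
  if (!file.exists(path)) {
    stop_wbi("file not found: ", path, class = "wbi_io_error")
  }
  args <- c(list(file = path, colClasses = "character",
                 check.names = FALSE, fileEncoding = "UTF-8"),
            dialect)
  df <- do.call(utils::read.csv, args)
  new_cohort(df, label = label)
}

#' Write a respondent cohort to CSV
#'
#' Serializes a cohort with the canonical category labels; missing gender is
#' written as an empty cell. `read_cohort(write_cohort(c))` reproduces the
#' cohort field-for-field.
#'
#' @param cohort a `wbi_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "wbi_cohort"))
  df <- as.data.frame(lapply(cohort, function(col) {
    if (is.factor(col)) as.character(col) else col
  }), check.names = FALSE)
  df$gender[is.na(df$gender)] <- ""
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_wbi("cannot write cohort to ", path, ": ", conditionMessage(ok),
             class = "wbi_io_error")
  }
  invisible(path)
}

#' Tabulate cohort demographics
#'
#' Category counts and percentages for the demographic fields. Percentages are
#' computed over non-missing responses for each field separately (so with one
#' missing gender in 597 respondents, 321 men is 321/596 = 53.9%).
#'
#' @param cohort a `wbi_cohort`.
#' @return A tibble with columns `field`, `level`, `n`, `pct` (percent of the
#'   field's non-missing responses) and `n_missing`.
#' @export
summarize_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "wbi_cohort"), nrow(cohort) > 0)
  fields <- c("gender", "age_band", "years_in_practice", "setting", "specialty")
  rows <- lapply(fields, function(f) {
    v <- cohort[[f]]
    n_miss <- sum(is.na(v))
    denom <- sum(!is.na(v))
    if (denom == 0) {
      warning(sprintf("field '%s' is entirely missing; no percentages", f))
      return(tibble::tibble(field = character(0), level = character(0),
                            n = integer(0), pct = numeric(0),
                            n_missing = integer(0)))
    }
    counts <- table(v)
    counts <- counts[counts > 0]   # report observed categories only
    tibble::tibble(field = f, level = names(counts),
                   n = as.integer(counts),
                   pct = 100 * as.integer(counts) / denom,
                   n_missing = n_miss)
  })
  do.call(rbind, rows)
}
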