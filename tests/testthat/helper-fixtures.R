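# one-row respondent data frame with sensible defaults
make_respondent <- function(id = "r1", gender = "man", age_band = "<35",
                            years = "<5", setting = "DSO-associate",
                            specialty = "general", wbi = rep("no", 7),
                            meaning = "neutral", wli = "neutral",
                            qol = 7, fatigue = 7, ee = "never", dp = "never",
                            si = "no", err = "no", itl = "none") {
  df <- data.frame(id = id, gender = gender, age_band = age_band,
                   years_in_practice = years, setting = setting,
                   specialty = specialty, stringsAsFactors = FALSE)
  for (j in 1:7) df[[paste0("wbi", j)]] <- wbi[j]
  df$wbi_meaning <- meaning; df$wbi_wli <- wli
  df$qol <- qol; df$fatigue <- fatigue
  df$ee_freq <- ee; df$dp_freq <- dp
  df$suicidal_ideation <- si; df$major_error <- err
  df$intent_to_leave <- itl
  df
}

# cohort built by stacking make_respondent rows; `...` are vectorized fields
# (genders alternate by default so gender-matched thresholds are derivable)
make_cohort_df <- function(n, ...) {
  args <- list(...)
  if (is.null(args$gender)) {
    args$gender <- rep(c("man", "woman"), length.out = max(n, 2))
  }
  rows <- lapply(seq_len(n), function(i) {
    a <- lapply(args, function(v) {
      if (is.list(v)) v[[i]] else v[[min(i, length(v))]]
    })
    do.call(make_respondent, c(list(id = paste0("r", i)), a))
  })
  do.call(rbind, rows)
}

# expand a score-stratum table into per-respondent scores + outcome flags
# (an open top stratum is encoded at its lower bound)
expand_table <- function(tab) {
  list(scores = rep(tab$lo, times = tab$n_pos + tab$n_neg),
       outcome = unlist(lapply(seq_len(nrow(tab)), function(i) {
         c(rep(TRUE, tab$n_pos[i]), rep(FALSE, tab$n_neg[i]))
       })))
}

# independent pairwise AUC oracle on raw score vectors
auc_oracle <- function(case_scores, control_scores) {
  total <- 0
  for (x in case_scores) {
    for (y in control_scores) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(case_scores) * length(control_scores))
}

# independent Fisher oracle: explicit enumeration of all tables with the
# observed margins, point probabilities from log-binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  as <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, as) + lchoose(r2, c1 - as) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[as == a]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# independent exact Wilcoxon oracle: enumerate group assignments of the
# pooled observations and recompute U for each
wilcoxon_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# random small score-stratum table with both classes non-empty
random_score_table <- function(max_n = 50, n_strata = sample(2:6, 1)) {
  repeat {
    n_pos <- stats::rpois(n_strata, max_n / (2 * n_strata))
    n_neg <- stats::rpois(n_strata, max_n / (2 * n_strata))
    keep <- n_pos + n_neg > 0
    if (sum(keep) >= 2 && sum(n_pos) > 0 && sum(n_neg) > 0 &&
        sum(n_pos + n_neg) <= max_n) {
      lo <- seq_len(sum(keep))
      return(wbiscreen:::new_score_table(lo, lo, n_pos[keep], n_neg[keep]))
    }
  }
}
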