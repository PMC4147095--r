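# Shared fixtures and independent oracles.

K_COLS <- paste0("K", sprintf("%02d", 1:10))
G_COLS <- paste0("G0", 1:8)

# A blank cohort in the schema layout: everything missing/NA except ids.
blank_cohort <- function(n, bank = default_item_bank()) {
  cohort <- tibble::tibble(
    respondent_id = sprintf("T%03d", seq_len(n)),
    timepoint = "test", arm = "none", mode = "in_person",
    age = 60, sex = NA_character_, education = NA_character_,
    race = NA_character_, screening_history = NA_character_
  )
  for (k in knowledge_cols(bank)) cohort[[k]] <- NA_character_
  for (g in goal_cols(bank)) cohort[[g]] <- NA_integer_
  cohort$top_three <- NA_character_
  cohort$decision_maker <- NA_character_
  cohort$involvement_level <- NA_integer_
  cohort
}

# Fill the first `n_correct` knowledge items with the keyed answer, the
# next `n_wrong` with a wrong option, leave the rest missing.
answer_items <- function(cohort, bank, row = 1, n_correct = 0, n_wrong = 0) {
  items <- knowledge_cols(bank)
  stopifnot(n_correct + n_wrong <= length(items))
  for (j in seq_len(n_correct)) {
    cohort[[items[j]]][row] <- bank$knowledge_items$correct_option[j]
  }
  for (j in seq_len(n_wrong)) {
    jj <- n_correct + j
    key <- bank$knowledge_items$correct_option[jj]
    cohort[[items[jj]]][row] <- setdiff(bank$knowledge_items$options[[jj]], key)[1]
  }
  cohort
}

# --- Independent oracles -------------------------------------------------

# ICC(A,1) with mean squares taken from a fitted two-way ANOVA, not from
# the package's direct sums-of-squares computation.
icc_oracle_aov <- function(test, retest) {
  n <- length(test)
  long <- data.frame(
    value = c(test, retest),
    subject = factor(rep(seq_len(n), 2)),
    occasion = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(value ~ subject + occasion, data = long))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Two-sided Fisher p-value by full hypergeometric enumeration over all
# tables with the observed margins.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct per-respondent re-derivation of the match rule from model
# coefficients, no matrix algebra, no package prediction code.
match_oracle <- function(model, cohort) {
  out <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    lp <- model$intercept
    for (g in model$covariate_goals) {
      rating <- cohort[[g]][i]
      if (is.na(rating)) rating <- model$goal_medians[[g]]
      lp <- lp + model$coefficients[[g]] * rating
    }
    p <- 1 / (1 + exp(-lp))
    obs <- cohort$screening_history[i]
    out[i] <- (p > 0.5 && identical(obs, "colonoscopy")) ||
      (p <= 0.5 && identical(obs, "other_test"))
  }
  out
}

ft_counts_row <- function(sample_name) {
  ft <- field_test_counts()
  row <- ft[ft$sample == sample_name, ]
  list(n = row$n, counts = unlist(row[K_COLS]))
}
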