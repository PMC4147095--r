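#' Discriminant-validity contrast of mean knowledge scores
#'
#' Welch two-sample t-test comparing mean knowledge between two cohorts
#' known to differ (decision-aid vs control arm; providers vs patients).
#' Undefined scores are excluded.
#'
#' @param scores_a,scores_b [score_knowledge()] results (or numeric score
#'   vectors) for the two groups; the estimate is `mean(a) - mean(b)`.
#' @param contrast_id label carried into the result.
#' @param conf confidence level.
#' @return tibble with one row: `contrast_id`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`, `estimate`, `ci_low`, `ci_high`, `p_value`, `test`.
#' @export
knowledge_contrast <- function(scores_a, scores_b, contrast_id = "contrast",
                               conf = 0.95) {
  a <- if (is.data.frame(scores_a)) scores_a$score_pct else as.numeric(scores_a)
  b <- if (is.data.frame(scores_b)) scores_b$score_pct else as.numeric(scores_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) abort_data("each cohort needs at least 2 defined scores")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # t.test errors on two constant samples; equal constants mean no
    # evidence of a difference, unequal constants a certain one.
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(contrast_id = contrast_id, mean_a = mean(a), mean_b = mean(b),
                          n_a = length(a), n_b = length(b),
                          estimate = mean(a) - mean(b),
                          ci_low = mean(a) - mean(b), ci_high = mean(a) - mean(b),
                          p_value = if (same) 1 else 0,
                          test = "Welch two-sample t-test (degenerate: constant scores)"))
  }
  tt <- stats::t.test(a, b, conf.level = conf)
  tibble::tibble(
    contrast_id = contrast_id,
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    estimate = unname(tt$estimate[1] - tt$estimate[2]),
    ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
    p_value = tt$p.value,
    test = "Welch two-sample t-test"
  )
}

#' Construct validity: decision involvement vs decision quality
#'
#' Tests whether respondents with high decision quality were less likely
#' to report that the doctor made the screening decision, using Fisher's
#' exact test on the 2x2 table of high-quality status by doctor-made
#' decision.
#'
#' @param high_quality logical vector (one element per respondent).
#' @param decision_maker character vector with levels
#'   `"patient"`, `"doctor"`, `"shared"`; the contrast is doctor vs not.
#' @return tibble with one row: the two doctor-made-decision proportions,
#'   their difference, the Fisher p-value and the table cells.
#' @export
involvement_association <- function(high_quality, decision_maker) {
  ok <- !is.na(high_quality) & !is.na(decision_maker)
  hq <- high_quality[ok]
  doctor <- decision_maker[ok] == "doctor"
  if (!any(hq) || all(hq)) abort_data("both high-quality and non-high-quality respondents are needed")
  tab <- table(factor(hq, levels = c(TRUE, FALSE)),
               factor(doctor, levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  p_hq <- mean(doctor[hq])
  p_not <- mean(doctor[!hq])
  tibble::tibble(
    contrast_id = "doctor_made_decision_by_decision_quality",
    pct_doctor_high_quality = 100 * p_hq,
    pct_doctor_not_high_quality = 100 * p_not,
    estimate = 100 * (p_hq - p_not),
    n_high_quality = sum(hq), n_not_high_quality = sum(!hq),
    p_value = ft$p.value,
    test = "Fisher's exact test"
  )
}

#' Response-rate arithmetic
#'
#' @param n_responded,n_invited integer counts.
#' @return list with the counts and `rate_pct` (unrounded).
#' @export
response_rate <- function(n_responded, n_invited) {
  if (n_invited <= 0) abort_data("n_invited must be positive")
  if (n_responded < 0 || n_responded > n_invited) abort_data("n_responded must lie in [0, n_invited]")
  list(n_responded = n_responded, n_invited = n_invited,
       rate_pct = 100 * n_responded / n_invited)
}

#' Feasibility report: missing-data rates overall and by mode
#'
#' Mean per-respondent fraction of missing knowledge items and missing
#' goal ratings, overall and stratified by mode of administration. When
#' exactly two modes are present, each scale's respondent-level missing
#' fractions are compared across modes with a Welch t-test (the mode
#' effect).
#'
#' @param cohort respondent data frame.
#' @param bank a `crcdqi_bank`.
#' @param n_invited optional number invited, for the response rate.
#' @return list with `overall` (tibble: scale, mean missing %), `by_mode`
#'   (tibble), `mode_effect` (tibble of Welch comparisons, or NULL),
#'   `response` (list or NULL).
#' @export
feasibility_report <- function(cohort, bank, n_invited = NULL) {
  cohort <- as_cohort(cohort, bank)
  kmiss <- rowMeans(is.na(as.matrix(cohort[knowledge_cols(bank)])))
  gmiss <- rowMeans(is.na(as.matrix(cohort[goal_cols(bank)])))

  overall <- tibble::tibble(
    scale = c("knowledge", "goals"),
    missing_pct = 100 * c(mean(kmiss), mean(gmiss)),
    n = nrow(cohort)
  )
  by_mode <- dplyr::bind_rows(lapply(split(seq_len(nrow(cohort)), cohort$mode), function(idx) {
    tibble::tibble(
      mode = cohort$mode[idx[1]],
      scale = c("knowledge", "goals"),
      missing_pct = 100 * c(mean(kmiss[idx]), mean(gmiss[idx])),
      n = length(idx)
    )
  }))

  mode_effect <- NULL
  modes <- unique(cohort$mode[!is.na(cohort$mode)])
  if (length(modes) == 2L) {
    i1 <- which(cohort$mode == modes[1]); i2 <- which(cohort$mode == modes[2])
    cmp1 <- missing_rate_test(kmiss[i1], kmiss[i2])
    cmp2 <- missing_rate_test(gmiss[i1], gmiss[i2])
    mode_effect <- tibble::tibble(
      scale = c("knowledge", "goals"),
      mode_a = modes[1], mode_b = modes[2],
      missing_pct_a = 100 * c(mean(kmiss[i1]), mean(gmiss[i1])),
      missing_pct_b = 100 * c(mean(kmiss[i2]), mean(gmiss[i2])),
      p_value = c(cmp1, cmp2),
      test = "Welch two-sample t-test on respondent missing fractions"
    )
  }

  list(
    overall = overall, by_mode = by_mode, mode_effect = mode_effect,
    response = if (!is.null(n_invited)) response_rate(nrow(cohort), n_invited)
  )
}

missing_rate_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b)$p.value
}

#' Item retention screen
#'
#' Flags instrument items for the retention review: knowledge items whose
#' difficulty exceeds the too-easy bar (cohort proportion correct > 0.85);
#' goals with a ceiling effect (share of respondents giving the maximum
#' rating above the ceiling threshold); goals that are drop candidates
#' because few respondents name them among their top three; and item
#' pairs whose inter-item correlation marks them as redundant. Flags are
#' deterministic functions of the data and thresholds; deletion is a user
#' action, never automatic. Ceiling-flagged goals that clear the top-three
#' bar are marked `retain` (high stated importance arbitrates in their
#' favor), matching how ceiling-affected goals were retained in the field
#' test.
#'
#' @param cohort respondent data frame (minimum size enforced).
#' @param bank a `crcdqi_bank`.
#' @param too_easy difficulty threshold for knowledge items (default 0.85).
#' @param ceiling share-at-maximum threshold for goals (default 0.50).
#' @param top_three_min minimum top-three percentage below which a goal is
#'   a drop candidate (default 10).
#' @param redundancy absolute inter-item correlation threshold (default 0.8).
#' @param min_n minimum cohort size (default 30).
#' @return tibble of per-item diagnostics: `item_id`, `kind`, `metric`,
#'   `value`, `top_three_pct`, `redundant_with`, `max_abs_r`, `flag`
#'   (`retain`/`revise`/`drop_candidate`).
#' @export
item_retention_screen <- function(cohort, bank, too_easy = 0.85, ceiling = 0.50,
                                  top_three_min = 10, redundancy = 0.8,
                                  min_n = 30) {
  cohort <- as_cohort(cohort, bank)
  if (nrow(cohort) < min_n) {
    abort_data(sprintf("retention screen needs at least %d respondents, got %d", min_n, nrow(cohort)))
  }

  diff <- item_difficulty(cohort, bank)
  keys <- stats::setNames(bank$knowledge_items$correct_option, knowledge_cols(bank))
  correct <- sweep(as.matrix(cohort[knowledge_cols(bank)]), 2, keys, `==`)
  correct[is.na(correct)] <- FALSE
  storage.mode(correct) <- "double"
  k_red <- max_abs_correlation(correct)

  goals <- as.matrix(cohort[goal_cols(bank)])
  storage.mode(goals) <- "double"
  smax <- bank$goal_items$scale_max[1]
  at_ceiling <- colMeans(goals == smax, na.rm = TRUE)
  g_red <- max_abs_correlation(goals)

  tt <- lapply(cohort$top_three, parse_top_three)
  top3_pct <- vapply(goal_cols(bank), function(g) {
    100 * mean(vapply(tt, function(sel) g %in% sel, TRUE))
  }, 0)

  k_rows <- tibble::tibble(
    item_id = diff$item_id, kind = "knowledge",
    metric = "difficulty", value = diff$difficulty,
    top_three_pct = NA_real_,
    redundant_with = k_red$partner, max_abs_r = k_red$max_r
  )
  k_rows$flag <- ifelse(k_rows$value > too_easy | k_rows$max_abs_r > redundancy,
                        "revise", "retain")

  g_rows <- tibble::tibble(
    item_id = goal_cols(bank), kind = "goal",
    metric = "share_at_ceiling", value = at_ceiling,
    top_three_pct = unname(top3_pct),
    redundant_with = g_red$partner, max_abs_r = g_red$max_r
  )
  g_rows$flag <- "retain"
  g_rows$flag[g_rows$value > ceiling & g_rows$top_three_pct < top_three_min] <- "revise"
  g_rows$flag[g_rows$top_three_pct < top_three_min & g_rows$value <= ceiling] <- "drop_candidate"
  g_rows$flag[g_rows$max_abs_r > redundancy] <- "revise"

  dplyr::bind_rows(k_rows, g_rows)
}

# Per-column maximum absolute pairwise correlation and the partner
# achieving it; constant columns yield NA.
max_abs_correlation <- function(m) {
  if (ncol(m) < 2L) {
    return(list(max_r = rep(NA_real_, ncol(m)), partner = rep(NA_character_, ncol(m))))
  }
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cm) <- NA
  max_r <- apply(abs(cm), 2, function(col) if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  partner <- colnames(cm)[apply(abs(cm), 2, function(col) if (all(is.na(col))) NA_integer_ else which.max(col))]
  partner[is.na(max_r)] <- NA_character_
  list(max_r = unname(max_r), partner = partner)
}

#' Brief-version reproducibility
#'
#' Pearson correlation between each respondent's brief (five-item) and
#' full (ten-item) knowledge scores, over respondents with both defined.
#' When a paired retest cohort is supplied the brief score's retest ICC is
#' recomputed as well.
#'
#' @param cohort respondent data frame (test timepoint).
#' @param bank a `crcdqi_bank`.
#' @param retest optional respondent data frame for the retest occasion
#'   (same respondent ids).
#' @return list with `pearson_r` (`NA` with a message when either score is
#'   constant), `n`, `brief_mean_pct`, `full_mean_pct`, and `brief_icc`
#'   (tibble or NULL).
#' @export
brief_reproducibility <- function(cohort, bank, retest = NULL) {
  full <- score_knowledge(cohort, bank)
  brief <- score_brief(cohort, bank)
  ok <- !is.na(full$score_pct) & !is.na(brief$score_pct)
  if (sum(ok) < 3L) abort_data("need at least 3 respondents with both scores defined")
  r <- if (stats::sd(full$score_pct[ok]) == 0 || stats::sd(brief$score_pct[ok]) == 0) {
    NA_real_
  } else {
    stats::cor(full$score_pct[ok], brief$score_pct[ok])
  }
  brief_icc <- NULL
  if (!is.null(retest)) {
    retest_scores <- score_brief(retest, bank)
    common <- intersect(brief$respondent_id, retest_scores$respondent_id)
    brief_icc <- retest_reliability(
      brief$score_pct[match(common, brief$respondent_id)],
      retest_scores$score_pct[match(common, retest_scores$respondent_id)],
      measure_id = "knowledge_score_brief"
    )
  }
  list(pearson_r = r, n = sum(ok),
       brief_mean_pct = mean(brief$score_pct[ok]),
       full_mean_pct = mean(full$score_pct[ok]),
       note = if (is.na(r)) "correlation undefined: constant scores",
       brief_icc = brief_icc)
}
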