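bank <- default_item_bank()

# model with all slopes 0: predicted probability is plogis(intercept)
flat_model <- function(p) {
  as_preference_model(log(p / (1 - p)),
                      setNames(rep(0, 7), paste0("G0", 1:7)), bank)
}

screened_record <- function(history, ratings = 5L, age = 60) {
  rec <- blank_cohort(1, bank)
  rec$age <- age
  rec$screening_history <- history
  for (g in G_COLS) rec[[g]] <- as.integer(ratings)
  rec
}

test_that("match rule: threshold at 0.5, ties to other test, never-screened never match", {
  cases <- list(
    list(p = 0.6, obs = "colonoscopy", match = TRUE, implied = "colonoscopy"),
    list(p = 0.6, obs = "other_test", match = FALSE, implied = "colonoscopy"),
    list(p = 0.5, obs = "other_test", match = TRUE, implied = "other_test"),
    list(p = 0.5, obs = "colonoscopy", match = FALSE, implied = "other_test"),
    list(p = 0.4, obs = "other_test", match = TRUE, implied = "other_test"),
    list(p = 0.9, obs = "never", match = FALSE, implied = "colonoscopy"),
    list(p = 0.1, obs = "never", match = FALSE, implied = "other_test")
  )
  for (case in cases) {
    res <- classify_match(flat_model(case$p), screened_record(case$obs), bank)
    expect_equal(res$predicted_prob, case$p, tolerance = 1e-12)
    expect_equal(res$implied_preference, case$implied)
    expect_equal(res$match, case$match)
    expect_true(res$eligible)
  }
})

test_that("respondents under the eligibility age are excluded", {
  res <- classify_match(flat_model(0.6), screened_record("colonoscopy", age = 49), bank)
  expect_false(res$eligible)
  expect_true(is.na(res$match))
})

test_that("one missing model goal is imputed, two make the probability undefined", {
  model <- as_preference_model(-5, c(G01 = 1), bank,
                               goal_medians = c(G01 = 6))
  rec <- screened_record("colonoscopy")
  rec$G01 <- NA_integer_
  res <- classify_match(model, rec, bank)
  expect_equal(res$predicted_prob, plogis(-5 + 6), tolerance = 1e-12)

  model2 <- as_preference_model(0, c(G01 = 0.5, G02 = -0.5), bank,
                                goal_medians = c(G01 = 6, G02 = 4))
  rec$G01 <- NA_integer_; rec$G02 <- NA_integer_
  expect_warning(res2 <- classify_match(model2, rec, bank), "excluded")
  expect_true(is.na(res2$predicted_prob))
  expect_false(res2$eligible)
})

test_that("fit recovers generating odds ratios from a large synthetic cohort", {
  truth <- list(intercept = -0.5,
                coefficients = c(G01 = log(1.83), G02 = log(0.70), G03 = 0,
                                 G04 = 0, G05 = 0, G06 = 0, G07 = 0))
  coh <- generate_cohort(cohort_spec(n = 2000, preference_truth = truth,
                                     never_frac = 0, seed = 42), bank)
  model <- fit_preference_model(coh, bank)
  expect_true(model$converged)
  ors <- exp(model$coefficients)
  expect_lt(abs(ors[["G01"]] / 1.83 - 1), 0.10)
  expect_lt(abs(ors[["G02"]] / 0.70 - 1), 0.10)
  expect_true(all(abs(model$coefficients[paste0("G0", 3:7)]) < 0.25))
})

test_that("repeated fits are unbiased and Wald intervals cover", {
  truth <- list(intercept = -0.5,
                coefficients = c(G01 = log(1.83), G02 = log(0.70), G03 = 0,
                                 G04 = 0, G05 = 0, G06 = 0, G07 = 0))
  z <- qnorm(0.975)
  est <- sapply(1:100, function(s) {
    coh <- generate_cohort(cohort_spec(n = 500, preference_truth = truth,
                                       never_frac = 0, missing_knowledge = 0,
                                       missing_goals = 0, seed = 1000 + s), bank)
    m <- fit_preference_model(coh, bank)
    se <- (log(m$or_table$or_high) - log(m$or_table$or_low)) / (2 * z)
    covered <- truth$coefficients >= m$coefficients - z * se &
      truth$coefficients <= m$coefficients + z * se
    c(m$coefficients, covered)
  })
  beta_mean <- rowMeans(est[1:7, ])
  expect_lt(abs(beta_mean[["G01"]] / log(1.83) - 1), 0.05)
  expect_lt(abs(beta_mean[["G02"]] / log(0.70) - 1), 0.05)
  expect_true(all(abs(beta_mean[paste0("G0", 3:7)]) < 0.05))
  coverage <- rowMeans(est[8:14, ])
  expect_true(all(coverage >= 0.90 & coverage <= 0.99))
})

test_that("degenerate cohorts are refused with informative errors", {
  coh <- dplyr::bind_rows(lapply(1:20, function(i) screened_record("colonoscopy")))
  coh$respondent_id <- sprintf("R%03d", 1:20)
  expect_error(fit_preference_model(coh, bank), "both outcome classes",
               class = "crcdqi_data_error")

  # constant ratings: slopes 0, intercept = log-odds of the base rate
  coh$screening_history[1:5] <- "other_test"
  model <- fit_preference_model(coh, bank)
  expect_true(all(model$coefficients == 0))
  expect_equal(model$intercept, log((15 / 20) / (5 / 20)), tolerance = 1e-9)
  expect_equal(sort(model$dropped_goals), sort(bank$model_goals))

  # perfectly separated outcome -> separation error, not a silent fit
  sep <- dplyr::bind_rows(lapply(1:30, function(i) {
    rec <- screened_record(if (i <= 15) "colonoscopy" else "other_test")
    rec$G01 <- if (i <= 15) 9L else 2L   # one goal separates the outcome
    rec
  }))
  sep$respondent_id <- sprintf("S%03d", 1:30)
  expect_error(fit_preference_model(sep, bank), "separation",
               class = "crcdqi_data_error")
})

test_that("match flags equal a brute-force re-derivation on small cohorts", {
  truth <- list(intercept = -0.5,
                coefficients = c(G01 = log(1.83), G02 = log(0.70), G03 = log(0.84),
                                 G04 = log(0.74), G05 = log(1.15), G06 = log(0.95),
                                 G07 = log(1.19)))
  model <- as_preference_model(truth$intercept, truth$coefficients, bank)
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_spec(n = 20, seed = seed, missing_goals = 0.05), bank)
    res <- suppressWarnings(classify_match(model, coh, bank))
    keep <- res$eligible
    expect_equal(res$match[keep], match_oracle(model, as.data.frame(coh))[keep])
  }
})

test_that("predicted probability is monotone in positively weighted goals", {
  model <- as_preference_model(-2, c(G01 = 0.6, G02 = -0.35), bank)
  set.seed(11)
  for (i in 1:25) {
    rec <- screened_record("colonoscopy", ratings = sample(0:9, 1))
    p0 <- predict_colonoscopy_prob(model, rec, bank)
    up <- rec; up$G01 <- up$G01 + 1L
    down <- rec; down$G02 <- down$G02 + 1L
    expect_gte(predict_colonoscopy_prob(model, up, bank), p0)
    expect_lte(predict_colonoscopy_prob(model, down, bank), p0)
  }
})

test_that("concordance summarization reproduces published percentages", {
  expect_equal(round_half_up(concordance_from_counts(71, 150)$concordance_pct, 1), 47.3)
  expect_equal(round_half_up(concordance_from_counts(35, 74)$concordance_pct, 1), 47.3)
  expect_error(concordance_from_counts(10, 0), class = "crcdqi_data_error")
})

test_that("noise-free cohorts classified under the generating model are 100% concordant", {
  spec <- cohort_spec(n = 300, decision_noise = 0, never_frac = 0,
                      missing_goals = 0, seed = 5)
  coh <- generate_cohort(spec, bank)
  truth_model <- as_preference_model(spec$preference_truth$intercept,
                                     spec$preference_truth$coefficients, bank)
  res <- concordance_score(coh, bank, model = truth_model)
  expect_equal(res$concordance_pct, 100)
  expect_equal(res$n_eligible, 300)
})

test_that("never-screened respondents count in the denominator and lean toward colonoscopy", {
  spec <- cohort_spec(n = 600, never_frac = 0.3, seed = 8, missing_goals = 0)
  coh <- generate_cohort(spec, bank)
  res <- concordance_score(coh, bank)
  n_never <- sum(coh$screening_history == "never")
  expect_equal(res$n_eligible, 600)
  expect_lte(res$concordance_pct, 100 * (600 - n_never) / 600)

  summ <- never_screened_preference_summary(res)
  expect_equal(summ$n_never, n_never)
  expect_equal(summ$pct_colonoscopy + summ$pct_other, 100)
  # the default generating regime leans toward colonoscopy
  expect_gt(summ$pct_colonoscopy, 50)

  # all never-screened with goals forcing colonoscopy preference
  allnever <- dplyr::bind_rows(lapply(1:10, function(i) screened_record("never", ratings = 9L)))
  allnever$respondent_id <- sprintf("N%02d", 1:10)
  model <- as_preference_model(-2, c(G01 = 0.6), bank)
  res2 <- concordance_score(allnever, bank, model = model)
  expect_equal(res2$concordance_pct, 0)
  expect_equal(never_screened_preference_summary(res2)$pct_colonoscopy, 100)
})
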