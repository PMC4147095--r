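#' Fit the goal-to-test-choice preference model
#'
#' Unpenalized maximum-likelihood logistic regression of screening group
#' (colonoscopy = 1 vs other test = 0) on the raw 0-10 importance ratings
#' of the model goals. The fit population is respondents aged 50 and older
#' who had a screening test; never-screened respondents are excluded from
#' the fit (they are classified later, not modelled). Ratings enter
#' unstandardized so each exponentiated coefficient is a per-point odds
#' ratio of choosing colonoscopy.
#'
#' Complete-case fitting: respondents missing any model-goal rating are
#' dropped from the fit (the fit-subset medians are retained for
#' single-value imputation at classification time). A goal with zero
#' variance in the fit subset is uninformative and enters with coefficient
#' 0. Complete or quasi-complete separation is reported as an error rather
#' than silently penalized.
#'
#' @param cohort respondent data frame.
#' @param bank a `crcdqi_bank`; `bank$model_goals` defines the covariates.
#' @param min_age eligibility age for the concordance analyses (default 50).
#' @return object of class `crcdqi_pref_model`: list with `covariate_goals`,
#'   `intercept`, `coefficients` (named log-odds per rating point),
#'   `or_table` (tibble of odds ratios with 95% Wald CIs), `goal_medians`
#'   (fit-subset medians used for imputation), `n_fit`, `converged`,
#'   `dropped_goals`, `min_age`.
#' @export
fit_preference_model <- function(cohort, bank, min_age = 50) {
  stopifnot(inherits(bank, "crcdqi_bank"))
  cohort <- as_cohort(cohort, bank)
  goals <- bank$model_goals

  fit_rows <- !is.na(cohort$age) & cohort$age >= min_age &
    !is.na(cohort$screening_history) &
    cohort$screening_history %in% c("colonoscopy", "other_test")
  dat <- cohort[fit_rows, c("screening_history", goals)]
  dat <- dat[stats::complete.cases(dat[goals]), , drop = FALSE]

  y <- as.integer(dat$screening_history == "colonoscopy")
  if (length(unique(y)) < 2L) {
    abort_data("preference model needs both outcome classes (colonoscopy and other_test) in the fit subset")
  }

  # Zero-variance covariates are collinear with the intercept; drop them
  # and report coefficient 0 rather than returning NA.
  variances <- vapply(goals, function(g) stats::var(dat[[g]]), 0)
  active <- goals[variances > 0]
  dropped <- goals[variances == 0]

  if (length(active)) {
    X <- dat[active]
    fit <- stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      abort_data(sprintf(
        "preference model is rank-deficient (aliased covariates: %s); remove collinear goals",
        paste(names(cf)[is.na(cf)], collapse = ", ")))
    }
    # Under (quasi-)separation the MLE does not exist: coefficients
    # diverge and every fitted probability saturates at 0 or 1.
    saturated <- all(fit$fitted.values < 1e-6 | fit$fitted.values > 1 - 1e-6)
    if (!fit$converged || saturated || any(abs(cf[-1]) > 10)) {
      abort_data(paste("separation detected in the preference model fit",
                       "(coefficient norm diverging); refit with fewer goal",
                       "covariates or use penalized estimation"))
    }
    se <- sqrt(diag(stats::vcov(fit)))
    intercept <- unname(cf[1])
    beta <- stats::setNames(rep(0, length(goals)), goals)
    beta[active] <- unname(cf[-1])
    se_full <- stats::setNames(rep(NA_real_, length(goals)), goals)
    se_full[active] <- unname(se[-1])
    converged <- fit$converged
  } else {
    p <- mean(y)
    intercept <- log(p / (1 - p))
    beta <- stats::setNames(rep(0, length(goals)), goals)
    se_full <- stats::setNames(rep(NA_real_, length(goals)), goals)
    converged <- TRUE
  }

  z <- stats::qnorm(0.975)
  or_table <- tibble::tibble(
    goal_id = goals,
    prompt = bank$goal_items$prompt[match(goals, bank$goal_items$goal_id)],
    log_odds = unname(beta),
    odds_ratio = exp(unname(beta)),
    or_low = exp(unname(beta) - z * unname(se_full)),
    or_high = exp(unname(beta) + z * unname(se_full))
  )

  structure(
    list(covariate_goals = goals, intercept = intercept, coefficients = beta,
         or_table = or_table,
         goal_medians = vapply(goals, function(g) stats::median(dat[[g]]), 0),
         n_fit = length(y), converged = converged, dropped_goals = dropped,
         min_age = min_age),
    class = "crcdqi_pref_model"
  )
}

#' Construct a preference model from known parameters
#'
#' Builds a `crcdqi_pref_model` directly from an intercept and named
#' log-odds coefficients, bypassing estimation. Used to classify cohorts
#' under a known generating model (e.g. the synthetic-data truth) or
#' under published coefficients.
#'
#' @param intercept log-odds intercept.
#' @param coefficients named numeric vector of log-odds per rating point;
#'   names must be goal ids of `bank`.
#' @param bank a `crcdqi_bank`.
#' @param goal_medians ratings used to impute a single missing model goal
#'   (default: scale midpoint for every goal).
#' @param min_age eligibility age (default 50).
#' @return a `crcdqi_pref_model`.
#' @export
as_preference_model <- function(intercept, coefficients, bank,
                                goal_medians = NULL, min_age = 50) {
  goals <- names(coefficients)
  if (is.null(goals) || !all(goals %in% goal_cols(bank))) {
    abort_config("coefficients must be named by goal ids present in the bank")
  }
  if (is.null(goal_medians)) {
    mid <- (bank$goal_items$scale_min[1] + bank$goal_items$scale_max[1]) / 2
    goal_medians <- stats::setNames(rep(mid, length(goals)), goals)
  }
  structure(
    list(covariate_goals = goals, intercept = intercept,
         coefficients = coefficients,
         or_table = tibble::tibble(
           goal_id = goals,
           prompt = bank$goal_items$prompt[match(goals, bank$goal_items$goal_id)],
           log_odds = unname(coefficients), odds_ratio = exp(unname(coefficients)),
           or_low = NA_real_, or_high = NA_real_),
         goal_medians = goal_medians, n_fit = 0L, converged = NA,
         dropped_goals = character(), min_age = min_age),
    class = "crcdqi_pref_model"
  )
}

#' @export
print.crcdqi_pref_model <- function(x, ...) {
  cat(sprintf("<crcdqi_pref_model> colonoscopy vs other test, n_fit = %d\n", x$n_fit))
  cat(sprintf("  intercept (log-odds): %.3f\n", x$intercept))
  print(x$or_table[, c("goal_id", "odds_ratio", "or_low", "or_high")])
  invisible(x)
}

#' Predicted probability of colonoscopy for each respondent
#'
#' Evaluates the fitted logistic form
#' `1 / (1 + exp(-(intercept + sum(beta * rating))))`. A single missing
#' model-goal rating is imputed with the fit-subset median; with two or
#' more missing the probability is undefined (`NA`).
#'
#' @param model a `crcdqi_pref_model`.
#' @param cohort respondent data frame.
#' @param bank a `crcdqi_bank`.
#' @return numeric vector of probabilities in `[0, 1]`, `NA` where undefined.
#' @export
predict_colonoscopy_prob <- function(model, cohort, bank) {
  stopifnot(inherits(model, "crcdqi_pref_model"))
  cohort <- as_cohort(cohort, bank)
  goals <- model$covariate_goals
  X <- as.matrix(cohort[goals])
  storage.mode(X) <- "double"
  n_missing <- rowSums(is.na(X))
  for (g in goals) {
    col <- match(g, goals)
    X[is.na(X[, col]), col] <- model$goal_medians[[g]]
  }
  lp <- model$intercept + drop(X %*% model$coefficients[goals])
  p <- 1 / (1 + exp(-lp))
  p[n_missing > 1L] <- NA_real_
  p
}

#' Classify screening decisions as matching stated goals or not
#'
#' A respondent aged `min_age` or older matches when the model-predicted
#' probability of colonoscopy exceeds 0.5 and they had a colonoscopy, or
#' the probability is at most 0.5 and they had some other test. The tie at
#' exactly 0.5 counts as an other-test preference. Never-screened
#' respondents receive a predicted probability and implied preference but
#' are never a match.
#'
#' @inheritParams predict_colonoscopy_prob
#' @return tibble with one row per input row: `respondent_id`, `eligible`
#'   (age >= `min_age` and a defined match), `predicted_prob`,
#'   `implied_preference` (`"colonoscopy"`/`"other_test"`), `observed`,
#'   `match` (logical, `NA` where undefined).
#' @export
classify_match <- function(model, cohort, bank) {
  cohort <- as_cohort(cohort, bank)
  p <- predict_colonoscopy_prob(model, cohort, bank)
  implied <- ifelse(p > 0.5, "colonoscopy", "other_test")
  observed <- cohort$screening_history
  old_enough <- !is.na(cohort$age) & cohort$age >= model$min_age

  match <- rep(NA, nrow(cohort))
  defined <- old_enough & !is.na(p) & !is.na(observed)
  match[defined] <- (p[defined] > 0.5 & observed[defined] == "colonoscopy") |
    (p[defined] <= 0.5 & observed[defined] == "other_test")
  # "never" falls through both arms of the rule: match stays FALSE.

  n_skipped <- sum(old_enough & (is.na(p) | is.na(observed)))
  if (n_skipped > 0) {
    warning(sprintf(
      "%d age-eligible respondent(s) excluded from concordance: undefined predicted probability or unknown screening history",
      n_skipped))
  }

  tibble::tibble(
    respondent_id = cohort$respondent_id,
    eligible = defined,
    predicted_prob = p,
    implied_preference = implied,
    observed = observed,
    match = match
  )
}

#' Cohort concordance score
#'
#' Fits the preference model on the cohort (or uses a supplied fit),
#' classifies every age-eligible respondent -- including the
#' never-screened, who count in the denominator but can never match -- and
#' summarizes the percentage whose screening decision matched their goals.
#'
#' @inheritParams fit_preference_model
#' @param model optional pre-fitted `crcdqi_pref_model`; fitted from
#'   `cohort` when omitted.
#' @return object of class `crcdqi_concordance`: list with `model`,
#'   `matches` (the [classify_match()] tibble), `n_eligible`, `n_match`,
#'   `concordance_pct` (unrounded).
#' @export
concordance_score <- function(cohort, bank, min_age = 50, model = NULL) {
  cohort <- as_cohort(cohort, bank)
  if (is.null(model)) model <- fit_preference_model(cohort, bank, min_age = min_age)
  matches <- classify_match(model, cohort, bank)
  n_eligible <- sum(matches$eligible)
  n_match <- sum(matches$match[matches$eligible])
  structure(
    list(model = model, matches = matches,
         n_eligible = n_eligible, n_match = n_match,
         concordance_pct = 100 * n_match / n_eligible),
    class = "crcdqi_concordance"
  )
}

#' @export
print.crcdqi_concordance <- function(x, ...) {
  cat(sprintf("<crcdqi_concordance> %d / %d matched (%.1f%%)\n",
              x$n_match, x$n_eligible, x$concordance_pct))
  invisible(x)
}

#' Summarize concordance from printed counts
#'
#' Arithmetic-only companion of [concordance_score()] for reproducing a
#' published summary from its numerator and denominator.
#'
#' @param n_match,n_eligible integer counts.
#' @return list with `n_match`, `n_eligible`, `concordance_pct` (unrounded).
#' @export
concordance_from_counts <- function(n_match, n_eligible) {
  if (n_eligible <= 0) abort_data("n_eligible must be positive")
  if (n_match < 0 || n_match > n_eligible) abort_data("n_match must lie in [0, n_eligible]")
  list(n_match = n_match, n_eligible = n_eligible,
       concordance_pct = 100 * n_match / n_eligible)
}

#' Implied test preference among the never-screened
#'
#' Among age-eligible respondents who have never been screened, the share
#' whose goals imply a colonoscopy preference (predicted probability >
#' 0.5) versus some other test.
#'
#' @param result a `crcdqi_concordance`.
#' @return list with `n_never`, `pct_colonoscopy`, `pct_other` (unrounded,
#'   summing to 100).
#' @export
never_screened_preference_summary <- function(result) {
  stopifnot(inherits(result, "crcdqi_concordance"))
  m <- result$matches
  never <- m$eligible & !is.na(m$observed) & m$observed == "never"
  if (!any(never)) abort_data("no never-screened eligible respondents")
  pct_col <- 100 * mean(m$implied_preference[never] == "colonoscopy")
  list(n_never = sum(never), pct_colonoscopy = pct_col, pct_other = 100 - pct_col)
}
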