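#' Specification of a synthetic respondent cohort
#'
#' Defines the generating process for one arm/mode cell of a synthetic
#' cohort with known ground truth: per-item correctness probabilities,
#' goal-rating distributions (discretized truncated normal plus a point
#' mass at the scale maximum to mimic ceiling behavior), a logistic
#' preference model linking goal ratings to the observed screening test,
#' a never-screened fraction, per-scale missingness, and retest
#' reliability targets.
#'
#' Screening assignment: with `decision_noise = NULL` (default) the
#' observed test among screened respondents is drawn Bernoulli from the
#' true model probability -- the data-generating process the fitted
#' logistic model assumes, so coefficient recovery is exact in
#' expectation. With a numeric `decision_noise` the observed test follows
#' the implied preference (probability thresholded at 0.5) and is flipped
#' with the given probability; `decision_noise = 0` therefore forces
#' downstream concordance to 100% among the screened.
#'
#' @param n cell size.
#' @param arm,mode study arm and administration mode of the cell.
#' @param mail_fraction fraction of the cell administered by mail instead
#'   of `mode` (used by the randomized online presets; default 0).
#' @param age_range integer age bounds.
#' @param p_age_50plus probability a respondent is 50 or older (ages are
#'   uniform within the chosen side of the 50 boundary).
#' @param item_probs named per-item probability of a correct response.
#' @param goal_distributions tibble with `goal_id`, `mean`, `sd`,
#'   `ceiling_mass` (see [default_goal_distributions()]).
#' @param preference_truth list with `intercept` and named `coefficients`
#'   (log-odds per rating point; see [default_preference_truth()]).
#' @param never_frac fraction of age-50+ respondents never screened.
#' @param decision_noise `NULL` for Bernoulli assignment, else flip
#'   probability in `[0, 1]` applied to the thresholded preference.
#' @param missing_knowledge,missing_goals per-response missingness rates.
#' @param retest_targets named population ICC targets per measure
#'   (`knowledge_score` plus goal ids; see [default_retest_targets()]).
#' @param goals_administered set `FALSE` for samples (providers) that
#'   complete only the knowledge items.
#' @param p_doctor_decision probability the respondent reports the doctor
#'   made the screening decision.
#' @param seed base RNG seed; stage-specific substreams are derived from
#'   it so that, e.g., toggling missingness cannot perturb earlier draws.
#' @return object of class `crcdqi_cohort_spec`.
#' @export
cohort_spec <- function(n = 150,
                        arm = c("none", "decision_aid", "control"),
                        mode = c("online", "mail", "in_person"),
                        mail_fraction = 0,
                        age_range = c(50, 75),
                        p_age_50plus = 1,
                        item_probs = NULL,
                        goal_distributions = default_goal_distributions(),
                        preference_truth = default_preference_truth(),
                        never_frac = 0.3,
                        decision_noise = NULL,
                        missing_knowledge = 0.002,
                        missing_goals = 0.002,
                        retest_targets = default_retest_targets(),
                        goals_administered = TRUE,
                        p_doctor_decision = 0.37,
                        seed = 1) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  if (is.null(item_probs)) {
    item_probs <- stats::setNames(rep(0.7, 10), paste0("K", sprintf("%02d", 1:10)))
  }
  check_prob <- function(x, field) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      abort_config(sprintf("'%s' must lie in [0, 1]", field))
    }
  }
  if (n < 1) abort_config("'n' must be at least 1")
  check_prob(item_probs, "item_probs")
  check_prob(never_frac, "never_frac")
  check_prob(p_age_50plus, "p_age_50plus")
  check_prob(mail_fraction, "mail_fraction")
  check_prob(missing_knowledge, "missing_knowledge")
  check_prob(missing_goals, "missing_goals")
  check_prob(goal_distributions$ceiling_mass, "goal_distributions$ceiling_mass")
  if (any(retest_targets < 0 | retest_targets > 1)) {
    abort_config("'retest_targets' must lie in [0, 1]")
  }
  if (!is.null(decision_noise)) check_prob(decision_noise, "decision_noise")

  structure(
    list(n = as.integer(n), arm = arm, mode = mode,
         mail_fraction = mail_fraction,
         age_range = as.integer(age_range), p_age_50plus = p_age_50plus,
         item_probs = item_probs, goal_distributions = goal_distributions,
         preference_truth = preference_truth, never_frac = never_frac,
         decision_noise = decision_noise,
         missing_knowledge = missing_knowledge, missing_goals = missing_goals,
         retest_targets = retest_targets,
         goals_administered = goals_administered,
         p_doctor_decision = p_doctor_decision,
         seed = as.integer(seed)),
    class = "crcdqi_cohort_spec"
  )
}

# Draw one goal rating column: point mass at the maximum, otherwise a
# clipped, rounded normal.
draw_goal_ratings <- function(n, mean, sd, ceiling_mass, smax = 10) {
  at_max <- stats::runif(n) < ceiling_mass
  raw <- round(stats::rnorm(n, mean, sd))
  raw <- pmin(pmax(raw, 0), smax)
  as.integer(ifelse(at_max, smax, raw))
}

#' Generate a synthetic respondent cohort
#'
#' Draws a cohort from a [cohort_spec()]: demographics and ages first,
#' then goal ratings, then screening history (never-screened thinning
#' followed by model-based test assignment among the screened), then
#' knowledge responses (independent per item at the spec probabilities),
#' then top-three selections and involvement, with missingness applied
#' last. Reproducible: the same spec (including seed) yields a
#' byte-identical cohort.
#'
#' @param spec a `crcdqi_cohort_spec`.
#' @param bank a `crcdqi_bank` (default packaged bank).
#' @param id_prefix prefix for respondent identifiers.
#' @return respondent tibble in the [response_schema()] layout, with
#'   `timepoint = "test"`.
#' @export
generate_cohort <- function(spec, bank = default_item_bank(), id_prefix = "R") {
  stopifnot(inherits(spec, "crcdqi_cohort_spec"))
  n <- spec$n
  seed <- spec$seed
  items <- knowledge_cols(bank)
  goals <- goal_cols(bank)
  missing_items <- setdiff(names(spec$item_probs), items)
  if (length(missing_items)) {
    abort_config(sprintf("item_probs names unknown to the bank: %s",
                         paste(missing_items, collapse = ", ")))
  }

  demo <- with_stage_seed(seed, "demographics", {
    over50 <- stats::runif(n) < spec$p_age_50plus
    lo <- spec$age_range[1]; hi <- spec$age_range[2]
    age <- integer(n)
    age[over50] <- sample(seq(max(lo, 50), hi), sum(over50), replace = TRUE)
    if (any(!over50)) {
      age[!over50] <- sample(seq(lo, min(hi, 49)), sum(!over50), replace = TRUE)
    }
    list(
      age = age,
      sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4)),
      education = sample(c("college_graduate", "some_college", "high_school_or_less"),
                         n, replace = TRUE, prob = c(0.45, 0.35, 0.20)),
      race = sample(c("white", "black", "other"), n, replace = TRUE,
                    prob = c(0.75, 0.18, 0.07)),
      mail = stats::runif(n) < spec$mail_fraction
    )
  })

  goal_mat <- with_stage_seed(seed, "goals", {
    gd <- spec$goal_distributions
    m <- sapply(goals, function(g) {
      row <- gd[gd$goal_id == g, ]
      if (nrow(row) == 0L) abort_config(sprintf("goal_distributions missing goal '%s'", g))
      draw_goal_ratings(n, row$mean, row$sd, row$ceiling_mass,
                        smax = bank$goal_items$scale_max[1])
    })
    matrix(as.integer(m), nrow = n, dimnames = list(NULL, goals))
  })

  screening <- with_stage_seed(seed, "screening", {
    truth <- spec$preference_truth
    cov_goals <- names(truth$coefficients)
    lp <- truth$intercept + drop(goal_mat[, cov_goals, drop = FALSE] %*% truth$coefficients)
    p <- 1 / (1 + exp(-lp))
    out <- rep(NA_character_, n)
    eligible <- demo$age >= 50 & spec$goals_administered
    never <- eligible & stats::runif(n) < spec$never_frac
    screened <- eligible & !never
    out[never] <- "never"
    if (is.null(spec$decision_noise)) {
      colo <- stats::runif(n) < p
    } else {
      colo <- (p > 0.5) != (stats::runif(n) < spec$decision_noise)
    }
    out[screened] <- ifelse(colo[screened], "colonoscopy", "other_test")
    out
  })

  know <- with_stage_seed(seed, "knowledge", {
    m <- sapply(items, function(k) {
      p <- spec$item_probs[[k]] %||% 0.7
      correct <- stats::runif(n) < p
      key <- bank$knowledge_items$correct_option[bank$knowledge_items$item_id == k]
      wrong <- setdiff(bank$knowledge_items$options[[match(k, items)]], key)[1]
      ifelse(correct, key, wrong)
    })
    matrix(as.character(m), nrow = n, dimnames = list(NULL, items))
  })

  top_three <- with_stage_seed(seed, "top_three", {
    vapply(seq_len(n), function(i) {
      if (!spec$goals_administered) return(NA_character_)
      # respondents name their three highest-rated goals, ties at random
      ord <- order(-goal_mat[i, ], stats::runif(length(goals)))
      paste(sort(goals[ord[1:3]]), collapse = ";")
    }, "")
  })

  involvement <- with_stage_seed(seed, "involvement", {
    dm <- sample(c("doctor", "shared", "patient"), n, replace = TRUE,
                 prob = c(spec$p_doctor_decision,
                          (1 - spec$p_doctor_decision) * 0.6,
                          (1 - spec$p_doctor_decision) * 0.4))
    list(decision_maker = dm,
         involvement_level = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.2, 0.35, 0.35)))
  })

  cohort <- tibble::tibble(
    respondent_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    timepoint = "test",
    arm = spec$arm,
    mode = ifelse(demo$mail, "mail", spec$mode),
    age = demo$age,
    sex = demo$sex, education = demo$education, race = demo$race,
    screening_history = screening
  )
  for (k in items) cohort[[k]] <- know[, k]
  for (g in goals) {
    cohort[[g]] <- if (spec$goals_administered) goal_mat[, g] else NA_integer_
  }
  cohort$top_three <- top_three
  cohort$decision_maker <- if (spec$goals_administered) involvement$decision_maker else NA_character_
  cohort$involvement_level <- if (spec$goals_administered) involvement$involvement_level else NA_integer_

  with_stage_seed(seed, "missingness", {
    if (spec$missing_knowledge > 0) {
      for (k in items) {
        drop <- stats::runif(n) < spec$missing_knowledge
        cohort[[k]][drop] <- NA_character_
      }
    }
    if (spec$missing_goals > 0 && spec$goals_administered) {
      for (g in goals) {
        drop <- stats::runif(n) < spec$missing_goals
        cohort[[g]][drop] <- NA_integer_
      }
    }
    cohort
  })
}

#' Generate a retest administration with a calibrated reliability
#'
#' Produces a second (`timepoint = "retest"`) administration for a cohort
#' generated by [generate_cohort()], with occasion noise calibrated so the
#' population ICC of each measure equals the spec's retest target. For a
#' target reliability `rho`, the retest value of a measure with test value
#' `x` is drawn as `mu + rho (x - mu) + sqrt(1 - rho^2) sigma z` with
#' `mu`, `sigma` the cohort mean and SD and `z` standard normal -- which
#' leaves the marginal distribution unchanged and sets the test-retest
#' correlation to `rho` -- and is then discretized back to the measure's
#' scale (item patterns for the knowledge score, integer 0-10 for goals).
#' Discretization attenuates the realized ICC slightly below the target;
#' a target of 1 reproduces the test administration exactly.
#'
#' @param cohort a cohort generated by [generate_cohort()].
#' @param spec the `crcdqi_cohort_spec` used to generate it.
#' @param bank a `crcdqi_bank`.
#' @return respondent tibble with `timepoint = "retest"`.
#' @export
generate_retest <- function(cohort, spec, bank = default_item_bank()) {
  stopifnot(inherits(spec, "crcdqi_cohort_spec"))
  cohort <- as_cohort(cohort, bank)
  targets <- spec$retest_targets
  if (any(targets < 0 | targets > 1)) abort_config("retest targets must lie in [0, 1]")
  n <- nrow(cohort)
  retest <- cohort
  retest$timepoint <- "retest"
  items <- knowledge_cols(bank)
  goals <- goal_cols(bank)

  with_stage_seed(spec$seed, "retest", {
    rho_k <- targets[["knowledge_score"]] %||% 1
    if (rho_k < 1) {
      keys <- stats::setNames(bank$knowledge_items$correct_option, items)
      resp <- as.matrix(cohort[items])
      correct <- sweep(resp, 2, keys, `==`)
      correct[is.na(correct)] <- FALSE
      s <- rowSums(correct) / length(items)
      mu <- mean(s); sdev <- stats::sd(s)
      if (sdev > 0) {
        s2 <- mu + rho_k * (s - mu) + sqrt(1 - rho_k^2) * sdev * stats::rnorm(n)
        s2 <- pmin(pmax(s2, 0), 1)
        k2 <- round(length(items) * s2)
        # realize each target count as an item pattern, keeping items that
        # were correct at test correct first, then promoting others
        new_correct <- matrix(FALSE, n, length(items))
        for (i in seq_len(n)) {
          ord <- order(!correct[i, ], stats::runif(length(items)))
          new_correct[i, ord[seq_len(k2[i])]] <- TRUE
        }
        for (j in seq_along(items)) {
          key <- keys[[items[j]]]
          wrong <- setdiff(bank$knowledge_items$options[[j]], key)[1]
          retest[[items[j]]] <- ifelse(new_correct[, j], key, wrong)
        }
      }
    }
    smax <- bank$goal_items$scale_max[1]
    for (g in goals) {
      x <- as.numeric(cohort[[g]])
      if (all(is.na(x))) next
      rho_g <- targets[[g]] %||% 1
      if (rho_g >= 1) next
      mu <- mean(x, na.rm = TRUE); sdev <- stats::sd(x, na.rm = TRUE)
      if (is.na(sdev) || sdev == 0) next
      y <- mu + rho_g * (x - mu) + sqrt(1 - rho_g^2) * sdev * stats::rnorm(n)
      retest[[g]] <- as.integer(pmin(pmax(round(y), 0), smax))
      retest[[g]][is.na(x)] <- NA_integer_
    }
    retest
  })
}

#' Deterministic cohort with fixed per-item correct counts
#'
#' Builds a cohort of `n` respondents in which each knowledge item is
#' answered correctly by exactly the requested number of respondents --
#' the structure of a published correct-count table. Which respondents
#' hold the correct answers is arbitrary (shuffled under `seed` when
#' given), which is exactly the point: the cohort mean knowledge score
#' depends only on the column sums, never on the joint assignment.
#'
#' @param counts named integer vector, `item_id -> number correct`.
#' @param n cohort size (each count must be in `0..n`).
#' @param bank a `crcdqi_bank`.
#' @param seed optional seed; when supplied the correct responses are
#'   assigned to random respondents, otherwise to the first `counts[j]`.
#' @return respondent tibble with every non-knowledge field constant.
#' @export
cohort_from_item_counts <- function(counts, n, bank = default_item_bank(), seed = NULL) {
  items <- knowledge_cols(bank)
  missing_items <- setdiff(items, names(counts))
  if (length(missing_items)) {
    abort_config(sprintf("counts missing item(s): %s", paste(missing_items, collapse = ", ")))
  }
  if (any(counts < 0 | counts > n)) abort_config("each count must lie in [0, n]")

  cohort <- tibble::tibble(
    respondent_id = sprintf("C%04d", seq_len(n)),
    timepoint = "test", arm = "none", mode = "in_person",
    age = 60, sex = NA_character_, education = NA_character_, race = NA_character_,
    screening_history = "colonoscopy"
  )
  assign_rows <- function(c_j) {
    if (is.null(seed)) seq_len(c_j) else sample.int(n, c_j)
  }
  do_assign <- function() {
    for (j in seq_along(items)) {
      k <- items[j]
      key <- bank$knowledge_items$correct_option[j]
      wrong <- setdiff(bank$knowledge_items$options[[j]], key)[1]
      resp <- rep(wrong, n)
      resp[assign_rows(counts[[k]])] <- key
      cohort[[k]] <<- resp
    }
  }
  if (is.null(seed)) do_assign() else with_stage_seed(seed, "assignment", do_assign())
  for (g in goal_cols(bank)) cohort[[g]] <- NA_integer_
  cohort$top_three <- NA_character_
  cohort$decision_maker <- NA_character_
  cohort$involvement_level <- NA_integer_
  cohort
}
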