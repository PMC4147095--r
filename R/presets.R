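# Field-test calibration constants: per-item correct-response counts
# observed in the instrument's published field test, used to parameterize
# the synthetic cohort presets and the count-fixed reference cohorts.

.field_test <- list(
  online_da = list(n = 163, counts = c(
    K01 = 150, K02 = 109, K03 = 155, K04 = 151, K05 = 140,
    K06 = 147, K07 = 156, K08 = 92, K09 = 136, K10 = 133)),
  online_control = list(n = 175, counts = c(
    K01 = 126, K02 = 63, K03 = 168, K04 = 125, K05 = 96,
    K06 = 115, K07 = 160, K08 = 72, K09 = 148, K10 = 53)),
  provider = list(n = 115, counts = c(
    K01 = 114, K02 = 66, K03 = 113, K04 = 109, K05 = 112,
    K06 = 111, K07 = 113, K08 = 100, K09 = 110, K10 = 73)),
  clinic = list(n = 94, counts = c(
    K01 = 50, K02 = 6, K03 = 81, K04 = 55, K05 = 28,
    K06 = 48, K07 = 70, K08 = 21, K09 = 71, K10 = 12))
)
.field_test$clinic$counts[["K09"]] <- 71

#' Published field-test correct-response counts
#'
#' Per-item counts of correct responses in the instrument's field-test
#' samples (decision-aid and control arms of the online study, the
#' provider sample, and the community-clinic sample). These counts
#' parameterize [cohort_preset()] and [cohort_from_item_counts()].
#'
#' @return tibble: `sample`, `n`, one column per knowledge item id holding
#'   the correct count.
#' @export
field_test_counts <- function() {
  dplyr::bind_rows(lapply(names(.field_test), function(nm) {
    tibble::as_tibble(c(list(sample = nm, n = .field_test[[nm]]$n),
                        as.list(.field_test[[nm]]$counts)))
  }))
}

# Default generating preference model: published per-point odds ratios for
# the seven model goals, with an intercept chosen to give roughly a 60:40
# colonoscopy:other split among screened respondents at the default
# goal-rating distributions (and a colonoscopy-leaning implied preference
# among the never screened).
default_preference_truth <- function() {
  list(
    intercept = -0.5,
    coefficients = c(
      G01 = log(1.83), G02 = log(0.70), G03 = log(0.84), G04 = log(0.74),
      G05 = log(1.15), G06 = log(0.95), G07 = log(1.19)
    )
  )
}

# Default goal-rating distributions: discretized truncated normals with a
# point mass at the scale maximum. Masses/means for G01, G03, G04 are set
# so that roughly 64%/56%/56% of respondents rate them 10 of 10 (the
# ceiling behavior seen in the field test); G08 is given a low, narrow
# distribution so only ~5% of respondents name it among their top three,
# the behavior of the field test's rarely-named goals.
default_goal_distributions <- function() {
  tibble::tibble(
    goal_id = paste0("G0", 1:8),
    mean = c(9.2, 5.5, 8.8, 9.0, 5.5, 6.0, 6.5, 3.5),
    sd = c(1.8, 3.0, 2.2, 1.8, 3.0, 3.0, 3.0, 2.0),
    ceiling_mass = c(0.35, 0.05, 0.30, 0.28, 0.05, 0.05, 0.08, 0.02)
  )
}

# Default retest reliability targets per measure (population ICCs the
# retest generator is calibrated to): the field test's knowledge-score and
# per-goal values.
default_retest_targets <- function() {
  c(knowledge_score = 0.67,
    G01 = 0.85, G02 = 0.74, G03 = 0.68, G04 = 0.87,
    G05 = 0.47, G06 = 0.61, G07 = 0.68, G08 = 0.55)
}

#' Synthetic cohort presets
#'
#' Ready-made [cohort_spec()]s parameterized from the field-test samples:
#' `"online_da"` and `"online_control"` (ages 35-70, half randomized to
#' mail), `"clinic"` (in-person, ages 50+), and `"provider"` (knowledge
#' items only; no goals or screening history).
#'
#' @param name preset name.
#' @param seed RNG seed stored in the spec.
#' @return a `crcdqi_cohort_spec` (list of cell specs for the online
#'   presets, which split across online and mail modes).
#' @export
cohort_preset <- function(name = c("online_da", "online_control", "clinic", "provider"),
                          seed = 1) {
  name <- match.arg(name)
  ft <- .field_test[[name]]
  probs <- ft$counts / ft$n
  switch(name,
    online_da = cohort_spec(
      n = ft$n, arm = "decision_aid", mode = "online", mail_fraction = 0.5,
      age_range = c(35, 70), p_age_50plus = 80 / 163,
      item_probs = probs, never_frac = 34 / 80, seed = seed),
    online_control = cohort_spec(
      n = ft$n, arm = "control", mode = "online", mail_fraction = 0.5,
      age_range = c(35, 70), p_age_50plus = 68 / 175,
      item_probs = probs, never_frac = 19 / 68, seed = seed),
    clinic = cohort_spec(
      n = ft$n, arm = "none", mode = "in_person",
      age_range = c(50, 80), p_age_50plus = 1,
      item_probs = probs, never_frac = 29 / 94,
      missing_knowledge = 0.032, missing_goals = 0.040, seed = seed),
    provider = cohort_spec(
      n = ft$n, arm = "none", mode = "mail",
      age_range = c(35, 70), p_age_50plus = 0.6,
      item_probs = probs, goals_administered = FALSE, seed = seed)
  )
}
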