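#' Score the CRC-DQI knowledge scale
#'
#' One point per keyed correct response; missing responses count as
#' incorrect; the score is standardized to 0-100% by dividing the number
#' correct by the number of items in the scale. A respondent who answered
#' fewer than half of the items does not receive a total score
#' (`score_pct = NA`). "At least half" with an odd item count is read
#' strictly: a score requires `n_answered >= ceiling(n_items / 2)`.
#'
#' @param cohort respondent data frame (one or more rows); see
#'   [response_schema()].
#' @param bank a `crcdqi_bank`.
#' @param items character vector of item ids defining the scale; defaults
#'   to the full bank.
#' @return tibble with one row per input row: `respondent_id`, `timepoint`,
#'   `n_items`, `n_answered`, `n_correct`, `score_pct` (0-100, unrounded,
#'   `NA` when undefined).
#' @export
score_knowledge <- function(cohort, bank, items = knowledge_cols(bank)) {
  stopifnot(inherits(bank, "crcdqi_bank"))
  if (nrow(bank$knowledge_items) == 0L) abort_config("item bank has no knowledge items")
  unknown <- setdiff(items, knowledge_cols(bank))
  if (length(unknown)) {
    abort_config(sprintf("unknown item id(s): %s", paste(unknown, collapse = ", ")))
  }
  cohort <- as_cohort(cohort, bank)
  keys <- stats::setNames(bank$knowledge_items$correct_option,
                          bank$knowledge_items$item_id)[items]
  n_items <- length(items)

  resp <- as.matrix(cohort[items])            # character matrix, NA = missing
  answered <- !is.na(resp)
  correct <- sweep(resp, 2, keys, `==`)
  correct[is.na(correct)] <- FALSE

  n_answered <- rowSums(answered)
  n_correct <- rowSums(correct)
  score <- 100 * n_correct / n_items
  score[n_answered < ceiling(n_items / 2)] <- NA_real_

  tibble::tibble(
    respondent_id = cohort$respondent_id,
    timepoint = cohort$timepoint %||% NA_character_,
    n_items = n_items,
    n_answered = as.integer(n_answered),
    n_correct = as.integer(n_correct),
    score_pct = score
  )
}

#' @rdname score_knowledge
#' @details `score_brief()` applies the identical rules restricted to the
#'   configured five-item brief subset, so a brief score is undefined when
#'   fewer than three of the five items were answered.
#' @export
score_brief <- function(cohort, bank) {
  score_knowledge(cohort, bank, items = bank$brief_subset)
}

#' Per-item difficulty (proportion correct) for a cohort
#'
#' The difficulty of a knowledge item is the fraction of the cohort that
#' answered it correctly, with missing responses counted as incorrect and
#' the full cohort size as denominator.
#'
#' @inheritParams score_knowledge
#' @return tibble: `item_id`, `n_correct`, `n`, `difficulty` (proportion in
#'   0-1).
#' @export
item_difficulty <- function(cohort, bank) {
  stopifnot(inherits(bank, "crcdqi_bank"))
  cohort <- as_cohort(cohort, bank)
  if (nrow(cohort) == 0L) abort_data("cohort is empty")
  items <- knowledge_cols(bank)
  keys <- stats::setNames(bank$knowledge_items$correct_option, items)
  resp <- as.matrix(cohort[items])
  correct <- sweep(resp, 2, keys, `==`)
  correct[is.na(correct)] <- FALSE
  tibble::tibble(
    item_id = items,
    n_correct = as.integer(unname(colSums(correct))),
    n = nrow(cohort),
    difficulty = unname(colSums(correct)) / nrow(cohort)
  )
}

#' Cohort mean knowledge score
#'
#' Mean of the defined per-respondent scores; respondents without a total
#' score (fewer than half the items answered) are excluded. When every
#' respondent has a defined score this equals 100 times the mean item
#' difficulty, whatever the joint distribution of correctness.
#'
#' @inheritParams score_knowledge
#' @return list with `mean_pct` (unrounded), `n_scored`, `n_total`.
#' @export
cohort_knowledge_mean <- function(cohort, bank, items = knowledge_cols(bank)) {
  scores <- score_knowledge(cohort, bank, items = items)
  defined <- !is.na(scores$score_pct)
  if (!any(defined)) abort_data("no respondent has a defined knowledge score")
  list(mean_pct = mean(scores$score_pct[defined]),
       n_scored = sum(defined), n_total = nrow(scores))
}
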