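#' Knowledge threshold defining "well-informed"
#'
#' The composite decision-quality indicator calls a respondent informed
#' when their knowledge score is at or above the mean knowledge score of a
#' designated reference cohort -- by construction the decision-aid arm,
#' whose members saw the full educational material. An explicit override
#' replaces the derived mean.
#'
#' @param reference_scores a [score_knowledge()] result for the reference
#'   (decision-aid) cohort, or a numeric vector of scores on the 0-100
#'   scale.
#' @param override optional explicit threshold percentage; returned as-is.
#' @return threshold percentage (unrounded).
#' @export
dqi_threshold <- function(reference_scores, override = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  scores <- if (is.data.frame(reference_scores)) reference_scores$score_pct else as.numeric(reference_scores)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) abort_data("reference cohort has no defined knowledge scores")
  mean(scores)
}

#' Composite decision-quality indicator
#'
#' A respondent made a high-quality decision when they were both
#' well-informed (unrounded knowledge score at or above the threshold --
#' the boundary is inclusive and compared before any display rounding) and
#' received a screening test that matched their goals. Respondents lacking
#' either a defined knowledge score or a defined match classification are
#' excluded from the summary denominator.
#'
#' @param knowledge a [score_knowledge()] result.
#' @param concordance a `crcdqi_concordance` (or its `matches` tibble)
#'   covering the same respondents.
#' @param threshold percentage from [dqi_threshold()].
#' @return object of class `crcdqi_dqi`: list with `per_respondent`
#'   (tibble: `respondent_id`, `knowledge_score`, `predicted_prob`,
#'   `informed`, `match`, `high_quality`), `threshold_used`,
#'   `n_high_quality`, `n_total`, `pct` (unrounded).
#' @export
decision_quality_summary <- function(knowledge, concordance, threshold) {
  matches <- if (inherits(concordance, "crcdqi_concordance")) concordance$matches else concordance
  stopifnot(is.data.frame(matches), is.data.frame(knowledge))

  only_k <- setdiff(knowledge$respondent_id, matches$respondent_id)
  only_m <- setdiff(matches$respondent_id, knowledge$respondent_id)
  if (length(only_k) || length(only_m)) {
    abort_data(sprintf(
      "knowledge and concordance inputs cover different respondents (only in knowledge: %s; only in concordance: %s)",
      paste(utils::head(only_k, 5), collapse = ", "),
      paste(utils::head(only_m, 5), collapse = ", ")))
  }

  merged <- dplyr::inner_join(
    knowledge[, c("respondent_id", "score_pct")],
    matches[, c("respondent_id", "eligible", "predicted_prob", "match")],
    by = "respondent_id"
  )
  merged$informed <- !is.na(merged$score_pct) & merged$score_pct >= threshold
  defined <- !is.na(merged$score_pct) & merged$eligible & !is.na(merged$match)
  merged$high_quality <- ifelse(defined, merged$informed & merged$match, NA)

  per_respondent <- tibble::tibble(
    respondent_id = merged$respondent_id,
    knowledge_score = merged$score_pct,
    predicted_prob = merged$predicted_prob,
    informed = merged$informed,
    match = merged$match,
    high_quality = merged$high_quality
  )
  n_total <- sum(defined)
  n_hq <- sum(merged$high_quality[defined])
  structure(
    list(per_respondent = per_respondent, threshold_used = threshold,
         n_high_quality = n_hq, n_total = n_total,
         pct = 100 * n_hq / n_total),
    class = "crcdqi_dqi"
  )
}

#' @export
print.crcdqi_dqi <- function(x, ...) {
  cat(sprintf("<crcdqi_dqi> %d / %d high decision quality (%.1f%%), informed threshold %.1f%%\n",
              x$n_high_quality, x$n_total, x$pct, x$threshold_used))
  invisible(x)
}
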