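#' Test-retest reliability (intraclass correlation coefficient)
#'
#' Agreement between two administrations of the same measure, quantified
#' by the single-measurement, absolute-agreement ICC from a two-way
#' random-effects decomposition (ICC(A,1) in the McGraw & Wong taxonomy).
#' With subjects `i = 1..n` crossed with occasions `j = 1..k` (`k = 2`
#' here), the mean squares for rows (subjects), columns (occasions) and
#' error give
#'
#'   ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))
#'
#' with the F-distribution-based confidence interval of McGraw & Wong
#' (1996). The decomposition is computed directly from sums of squares,
#' not via a fitted ANOVA object.
#'
#' @param test,retest numeric vectors of the measure at the two occasions;
#'   pairs with a missing value are dropped.
#' @param measure_id label carried into the result.
#' @param conf confidence level (default 0.95).
#' @param target reliability target reported alongside the estimate
#'   (default 0.7, the conventional adequacy bar).
#' @return tibble with one row: `measure_id`, `icc`, `ci_low`, `ci_high`,
#'   `n_pairs`, `model_form`, `target`, `meets_target`.
#' @export
retest_reliability <- function(test, retest, measure_id = "measure",
                               conf = 0.95, target = 0.7) {
  ok <- !is.na(test) & !is.na(retest)
  x <- cbind(as.numeric(test[ok]), as.numeric(retest[ok]))
  n <- nrow(x)
  if (n < 3L) abort_data("ICC needs at least 3 complete test/retest pairs")
  k <- 2L

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  SSR <- k * sum((row_means - grand)^2)
  SSC <- n * sum((col_means - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC

  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))

  if (MSR <= .Machine$double.eps * abs(grand + 1)) {
    warning(sprintf("zero between-subject variance for '%s'; ICC reported as 0", measure_id))
    return(tibble::tibble(measure_id = measure_id, icc = 0,
                          ci_low = NA_real_, ci_high = NA_real_,
                          n_pairs = n, model_form = "two-way random, absolute agreement, single measurement (ICC(A,1))",
                          target = target, meets_target = FALSE))
  }

  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  icc <- (MSR - MSE) / denom

  # McGraw & Wong (1996) F-based interval for ICC(A,1).
  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  Fj <- MSC / MSE
  v <- ((a * Fj + b)^2) /
    ((a^2 * Fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
  FU <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
  ci_low <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ci_high <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)

  tibble::tibble(
    measure_id = measure_id,
    icc = icc,
    ci_low = min(ci_low, icc),
    ci_high = max(ci_high, icc),
    n_pairs = n,
    model_form = "two-way random, absolute agreement, single measurement (ICC(A,1))",
    target = target,
    meets_target = icc > target
  )
}

#' Retest reliability of every instrument measure in a paired cohort
#'
#' Pairs each respondent's first (`test`) and second (`retest`)
#' administration and computes [retest_reliability()] for the total
#' knowledge score, the brief knowledge score and each goal rating.
#'
#' @param cohort respondent data frame containing both timepoints.
#' @param bank a `crcdqi_bank`.
#' @return tibble of ICC rows, one per measure.
#' @export
retest_reliability_report <- function(cohort, bank) {
  cohort <- as_cohort(cohort, bank)
  t1 <- cohort[cohort$timepoint == "test", ]
  t2 <- cohort[cohort$timepoint == "retest", ]
  common <- intersect(t1$respondent_id, t2$respondent_id)
  if (length(common) < 3L) abort_data("fewer than 3 respondents with both timepoints")
  t1 <- t1[match(common, t1$respondent_id), ]
  t2 <- t2[match(common, t2$respondent_id), ]

  rows <- list(
    retest_reliability(score_knowledge(t1, bank)$score_pct,
                       score_knowledge(t2, bank)$score_pct,
                       measure_id = "knowledge_score"),
    retest_reliability(score_brief(t1, bank)$score_pct,
                       score_brief(t2, bank)$score_pct,
                       measure_id = "knowledge_score_brief")
  )
  for (g in goal_cols(bank)) {
    rows[[length(rows) + 1L]] <- retest_reliability(t1[[g]], t2[[g]], measure_id = g)
  }
  dplyr::bind_rows(rows)
}
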