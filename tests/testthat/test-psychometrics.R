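bank <- default_item_bank()

test_that("ICC hits the exact anchors: perfect agreement, degenerate data, too-few pairs", {
  x <- c(10, 30, 50, 70, 90)
  res <- retest_reliability(x, x)
  expect_equal(res$icc, 1)
  expect_true(res$meets_target)

  expect_warning(res0 <- retest_reliability(c(4, 4, 4), c(6, 6, 6)),
                 "zero between-subject variance")
  expect_equal(res0$icc, 0)

  expect_error(retest_reliability(c(1, 2), c(1, 2)), "at least 3",
               class = "crcdqi_data_error")
})

test_that("ICC agrees with the ANOVA mean-squares oracle to 1e-9", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    latent <- rnorm(n, 50, 15)
    test <- latent + rnorm(n, 0, 8)
    retest <- latent + rnorm(n, sample(c(-4, 0, 4), 1), 8)
    expect_equal(retest_reliability(test, retest)$icc,
                 icc_oracle_aov(test, retest), tolerance = 1e-9)
  }
})

test_that("ICC of independent pairs is near zero and CIs behave", {
  set.seed(32)
  res <- retest_reliability(rnorm(500), rnorm(500))
  expect_lt(abs(res$icc), 0.1)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC recovers a strong latent reliability at the field-test retest size", {
  set.seed(33)
  est <- replicate(200, {
    latent <- rnorm(71, 0, sqrt(0.87))
    retest_reliability(latent + rnorm(71, 0, sqrt(0.13)),
                       latent + rnorm(71, 0, sqrt(0.13)))$icc
  })
  # the point target sits inside the central 95% of the sampling distribution
  expect_gt(quantile(est, 0.975), 0.87)
  expect_lt(quantile(est, 0.025), 0.87)
  expect_lt(abs(median(est) - 0.87), 0.03)
})

test_that("knowledge contrast: identical cohorts give difference 0, p = 1", {
  scores <- c(40, 60, 80, 90)
  res <- knowledge_contrast(scores, scores)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)
})

test_that("arm contrast lands in the published interval for most re-simulated cohorts", {
  da_probs <- ft_counts_row("online_da")
  ctrl_probs <- ft_counts_row("online_control")
  hits <- vapply(1:200, function(s) {
    da <- generate_cohort(cohort_spec(n = 163, arm = "decision_aid",
                                      item_probs = da_probs$counts / da_probs$n,
                                      missing_knowledge = 0, seed = 2000 + s), bank)
    ctrl <- generate_cohort(cohort_spec(n = 175, arm = "control",
                                        item_probs = ctrl_probs$counts / ctrl_probs$n,
                                        missing_knowledge = 0, seed = 7000 + s), bank)
    est <- knowledge_contrast(score_knowledge(da, bank), score_knowledge(ctrl, bank))$estimate
    est >= 12.1 && est <= 22.9
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("providers outscore online patients at the field-test difficulties", {
  prov <- ft_counts_row("provider")
  da <- ft_counts_row("online_da"); ctrl <- ft_counts_row("online_control")
  provider <- generate_cohort(cohort_spec(n = 115, item_probs = prov$counts / prov$n,
                                          goals_administered = FALSE,
                                          missing_knowledge = 0, seed = 61), bank)
  online <- dplyr::bind_rows(
    generate_cohort(cohort_spec(n = 163, item_probs = da$counts / da$n,
                                missing_knowledge = 0, seed = 62), bank),
    generate_cohort(cohort_spec(n = 175, item_probs = ctrl$counts / ctrl$n,
                                missing_knowledge = 0, seed = 63), bank)
  )
  res <- knowledge_contrast(score_knowledge(provider, bank),
                            score_knowledge(online, bank),
                            contrast_id = "provider_vs_online")
  expect_gt(res$estimate, 0)
  expect_lt(res$p_value, 0.001)
})

test_that("involvement association matches the hypergeometric oracle and published reconstruction", {
  # equal proportions in both groups
  res <- involvement_association(rep(c(TRUE, FALSE), each = 10),
                                 rep(c("doctor", "patient"), 10))
  expect_equal(res$p_value, 1)

  # perfectly associated table
  res2 <- involvement_association(rep(c(TRUE, FALSE), each = 10),
                                  c(rep("doctor", 10), rep("patient", 10)))
  expect_lt(res2$p_value, 0.001)
  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(res2$p_value, fisher_oracle(tab), tolerance = 1e-12)

  # table reconstructed from the published marginals: 29.7% of 32 doctor-made
  # decisions among high-quality vs 38.9% of 119 among the rest
  hq <- c(rep(TRUE, 32), rep(FALSE, 119))
  dm <- c(rep("doctor", 10), rep("shared", 22),
          rep("doctor", 46), rep("shared", 73))
  res3 <- involvement_association(hq, dm)
  expect_gt(res3$p_value, 0.05)
  expect_equal(res3$p_value,
               fisher_oracle(matrix(c(10, 46, 22, 73), 2)), tolerance = 1e-12)
})

test_that("Fisher p-values equal full enumeration on random small tables", {
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    while (sum(tab) > 50) tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("feasibility report: complete data, published response rates, mode effect", {
  coh <- answer_items(blank_cohort(10, bank), bank, n_correct = 0)
  for (i in 1:10) coh <- answer_items(coh, bank, row = i, n_correct = 10)
  for (g in G_COLS) coh[[g]] <- 5L
  rep0 <- feasibility_report(coh, bank)
  expect_true(all(rep0$overall$missing_pct == 0))

  expect_equal(round_half_up(response_rate(338, 367)$rate_pct), 92)
  expect_equal(round_half_up(response_rate(115, 193)$rate_pct, 1), 59.6)
  expect_error(response_rate(10, 0), class = "crcdqi_data_error")

  # higher missingness by mail than online shows up as a mode effect
  spec_mail <- cohort_spec(n = 120, mode = "mail", missing_knowledge = 0.10,
                           missing_goals = 0.002, seed = 71)
  spec_online <- cohort_spec(n = 120, mode = "online", missing_knowledge = 0.002,
                             missing_goals = 0.002, seed = 72)
  both <- dplyr::bind_rows(generate_cohort(spec_mail, bank, id_prefix = "M"),
                           generate_cohort(spec_online, bank, id_prefix = "O"))
  fr <- feasibility_report(both, bank)
  know_row <- fr$mode_effect[fr$mode_effect$scale == "knowledge", ]
  expect_lt(know_row$p_value, 0.001)
  goal_row <- fr$mode_effect[fr$mode_effect$scale == "goals", ]
  expect_gt(goal_row$p_value, 0.05)
})

test_that("retention screen flags too-easy items, ceilings and rarely-named goals", {
  coh <- generate_cohort(cohort_preset("online_da", seed = 81), bank)
  diag <- item_retention_screen(coh, bank)

  k <- diag[diag$kind == "knowledge", ]
  expected_easy <- item_difficulty(coh, bank)$difficulty > 0.85
  expect_equal(k$flag == "revise", expected_easy)
  expect_true(any(expected_easy))   # the easy items do trip the screen

  g <- diag[diag$kind == "goal", ]
  # the three ceiling-prone goals exceed 50% at the maximum but stay
  # retained because they are frequently named top-three
  ceiling_goals <- g$item_id[g$value > 0.5]
  expect_true(all(c("G01", "G03", "G04") %in% ceiling_goals))
  expect_true(all(g$flag[g$item_id %in% c("G01", "G03", "G04")] == "retain"))
  # the sedation goal is rarely a top-three pick: drop candidate
  expect_equal(g$flag[g$item_id == "G08"], "drop_candidate")

  expect_error(item_retention_screen(coh[1:10, ], bank), "at least 30",
               class = "crcdqi_data_error")
})

test_that("retention screen marks redundant twins and respects thresholds", {
  coh <- generate_cohort(cohort_spec(n = 200, seed = 82), bank)
  coh$G02 <- coh$G01    # duplicated goal: inter-item correlation 1
  diag <- item_retention_screen(coh, bank)
  g12 <- diag[diag$item_id %in% c("G01", "G02"), ]
  expect_true(all(g12$max_abs_r > 0.99))
  expect_true(all(g12$flag == "revise"))
  # flags are a pure function of data + thresholds
  expect_identical(diag, item_retention_screen(coh, bank))
})

test_that("brief version reproduces the full score and its own reliability", {
  # brief subset equal to the whole (restricted) bank: r = 1
  sub_bank <- bank
  sub_bank$knowledge_items <- bank$knowledge_items[match(bank$brief_subset, bank$knowledge_items$item_id), ]
  coh <- generate_cohort(cohort_spec(n = 80, seed = 91), bank)
  expect_equal(brief_reproducibility(coh, sub_bank)$pearson_r, 1)

  # full bank: correlated but not perfectly, stable under the seed
  rep1 <- brief_reproducibility(coh, bank)
  expect_gt(rep1$pearson_r, 0)
  expect_lt(rep1$pearson_r, 1)
  expect_equal(rep1$pearson_r,
               brief_reproducibility(generate_cohort(cohort_spec(n = 80, seed = 91), bank), bank)$pearson_r)

  # all-correct respondent scores 100 on the brief scale
  rec <- answer_items(blank_cohort(1, bank), bank, n_correct = 10)
  expect_equal(score_brief(rec, bank)$score_pct, 100)

  # with a retest administration the brief ICC is reported
  spec <- cohort_preset("online_da", seed = 92)
  test_adm <- generate_cohort(spec, bank)
  retest_adm <- generate_retest(test_adm, spec, bank)
  rep2 <- brief_reproducibility(test_adm, bank, retest = retest_adm)
  expect_s3_class(rep2$brief_icc, "tbl_df")
  expect_true(rep2$brief_icc$icc > 0 && rep2$brief_icc$icc < 1)
})
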