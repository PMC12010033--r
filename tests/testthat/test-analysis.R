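test_that("group comparison reproduces the toy-cohort hand calculation", {
  coh <- score_cohort(toy_cohort())
  # scores: survivors {0, 0, 3}, deceased {5, 7, 8} -- complete separation
  cmp <- compare_groups(coh, "died_within_1yr", method = "exact")
  expect_identical(cmp$groups$group, c("Survived", "Deceased"))
  expect_identical(cmp$groups$n, c(3L, 3L))
  expect_equal(cmp$u_statistic, 0)           # survivors never outrank
  expect_equal(cmp$p_value, oracle_mw_exact_p(c(0, 0, 3), c(5, 7, 8)))
  expect_equal(cmp$p_value, 2 / choose(6, 3))  # minimum attainable, two-sided
  expect_true(all(cmp$groups$p25 <= cmp$groups$median &
                    cmp$groups$median <= cmp$groups$p75))
})

test_that("a 4-patient cohort matches the enumeration oracle", {
  coh <- toy_cohort()[c(1, 2, 5, 6), ]
  coh$died_within_1yr <- c(FALSE, FALSE, TRUE, TRUE)
  coh$days_to_death <- c(NA, NA, 45L, 300L)
  sc <- score_cohort(coh)
  # survived scores {0, 0}; deceased {7, 8}
  cmp <- compare_groups(sc, "died_within_1yr", method = "exact")
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$p_value, oracle_mw_exact_p(c(0, 0), c(7, 8)))
  expect_equal(cmp$p_value, 1 / 3)
})

test_that("compare_groups requires both outcome levels", {
  coh <- toy_cohort()
  coh$wound_complication <- TRUE
  expect_error(compare_groups(coh, "wound_complication"), "single level")
  expect_error(compare_groups(coh, "not_a_field"))
})

test_that("mortality ROC honours orientation and the U identity", {
  coh <- score_cohort(toy_cohort())
  hi <- mortality_roc(coh, "higher_score_positive")
  expect_equal(hi$auc, 1)   # every deceased patient outscores every survivor
  lo <- mortality_roc(coh, "lower_score_positive")
  expect_equal(lo$auc, 0)

  # tie across classes on a 6-patient cohort: pair-counting oracle
  coh2 <- coh
  coh2$hypoxia[4] <- FALSE
  coh2$diabetes_mellitus[4] <- FALSE
  sc2 <- score_cohort(coh2)   # deceased scores now {3, 7, 8}, tie with survivor 3
  r2 <- mortality_roc(sc2)
  expect_equal(r2$auc, oracle_auc(sc2$total_score, sc2$died_within_1yr),
               tolerance = 1e-12)
  # cross-module identity AUC = U_deceased / (n+ * n-)
  cmp <- compare_groups(sc2, "died_within_1yr")
  u_deceased <- cmp$groups$n[1] * cmp$groups$n[2] - cmp$u_statistic
  expect_equal(r2$auc, u_deceased / prod(cmp$groups$n), tolerance = 1e-12)
})

test_that("katz correlation applies the early-death exclusion and accounting", {
  coh <- toy_cohort()
  kc <- katz_correlation(coh)
  expect_identical(kc$excluded_early_death_n, 1L)  # T05 died day 45
  expect_identical(kc$analyzable_n, 5L)
  expect_identical(kc$missing_katz_n, 0L)
  # Katz totals among the 5: {6,5,3,2,2} against scores {0,0,3,5,8}
  expect_equal(kc$result$r,
               stats::cor(rank(c(0, 0, 3, 5, 8)), rank(c(6, 5, 3, 2, 2))),
               tolerance = 1e-12)
  expect_lt(kc$result$r, 0)
  # accounting identity over the whole cohort
  expect_identical(kc$analyzable_n + kc$excluded_early_death_n +
                     kc$missing_katz_n, nrow(coh))

  few <- toy_cohort()[1:2, ]
  expect_error(katz_correlation(few), "fewer than 3")
})

test_that("age band summaries decompose the mean score exactly", {
  coh <- score_cohort(toy_cohort())
  b <- age_band_summaries(coh)
  expect_identical(b$band, c("under_65", "65_to_79", "over_79"))
  expect_identical(b$n, c(2L, 2L, 2L))
  comp_sum <- b$mean_age_points + b$mean_comorbidity_points +
    b$mean_mobilization_points + b$mean_complication_points
  expect_equal(comp_sum, b$mean_total_score, tolerance = 1e-9)

  young <- coh[coh$age_years < 65, ]
  b2 <- age_band_summaries(young)
  expect_identical(b2$n, c(2L, 0L, 0L))
  expect_true(all(is.na(b2$mean_total_score[2:3])))

  single <- coh[3, ]
  b3 <- age_band_summaries(single)
  expect_equal(b3$mean_total_score[2], coh$total_score[3])
})

test_that("the full analysis assembles all sections and degrades gracefully", {
  coh <- simulate_cohort(paper_like_config(seed = 42))
  rep <- run_full_analysis(coh)
  expect_s3_class(rep, "bka_analysis")
  expect_length(rep$comparisons, 4L)
  expect_s3_class(rep$roc, "bka_roc")
  expect_s3_class(rep$katz, "katz_correlation")
  expect_identical(nrow(rep$age_bands), 3L)
  expect_identical(rep$katz_excluded_n,
                   sum(coh$died_within_1yr & coh$days_to_death < 90,
                       na.rm = TRUE))

  # no Katz data: the correlation section is marked, the rest survives
  coh2 <- coh
  coh2[, grep("^katz_", names(coh2))] <- NA
  rep2 <- run_full_analysis(coh2)
  expect_s3_class(rep2$katz, "not_computable")
  expect_s3_class(rep2$roc, "bka_roc")
})

test_that("analysis reports are byte-identical across runs", {
  coh <- simulate_cohort(paper_like_config(seed = 42))
  d1 <- file.path(tempdir(), "rep1")
  d2 <- file.path(tempdir(), "rep2")
  write_analysis(run_full_analysis(coh), d1)
  write_analysis(run_full_analysis(coh), d2)
  for (f in c("scored_cohort.csv", "report.txt", "summary.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_true(file.exists(file.path(d1, "summary.json")))
  js <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_identical(js$cohort$n, 30L)
})
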