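test_that("cohort summaries reproduce the observed histology means", {
  rhi_t0 <- vapply(observed_rhi, `[`, 0, 1L)
  s <- summarize_cohort(rhi_t0)
  expect_equal(s$mean, 15.6364, tolerance = 1e-4)
  expect_equal(round(s$mean), 16) # printed rounded mean
  expect_equal(s$n, 11)
  expect_equal(s$minimum, 6)
  expect_equal(s$maximum, 23)
  # degenerate cases
  one <- summarize_cohort(5)
  expect_true(one$degenerate)
  expect_equal(one$std, 0)
  expect_equal(one$mean, 5)
  expect_equal(summarize_cohort(rep(3, 7))$std, 0)
  expect_error(summarize_cohort(numeric(0)), "no non-missing")
})

test_that("paired t and Pearson agree with from-definition oracles", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- x + rnorm(n, mean = runif(1, -1, 1))
    tt <- paired_t(x, y)
    or <- naive_paired_t(x, y)
    expect_equal(tt$statistic, or$statistic, tolerance = 1e-12)
    expect_equal(tt$df, or$df)
    expect_equal(tt$p_value, or$p_two, tolerance = 1e-12)
    expect_equal(paired_t(x, y, "one")$p_value, or$p_two / 2,
                 tolerance = 1e-12)
    pp <- pearson(x, y)
    expect_equal(pp$r, naive_pearson(x, y), tolerance = 1e-12)
    expect_equal(pp$p_value, naive_pearson_p_two(x, y), tolerance = 1e-12)
  }
})

test_that("tests respect their invariances and degeneracies", {
  set.seed(23)
  x <- rnorm(10); y <- rnorm(10, 1)
  # adding a common constant leaves the paired statistic unchanged
  expect_equal(paired_t(x + 5, y + 5)$statistic, paired_t(x, y)$statistic)
  # affine rescaling leaves Pearson r unchanged (up to slope sign)
  expect_equal(pearson(2 * x + 3, y)$r, pearson(x, y)$r, tolerance = 1e-12)
  expect_equal(pearson(x, -4 * y + 1)$r, -pearson(x, y)$r,
               tolerance = 1e-12)
  # exact linear relation
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # constant shift between pairs: t has the sign of the shift
  expect_gt(paired_t(x + 2, x + rnorm(10, 0, 1e-6))$statistic, 0)
  expect_error(paired_t(x, x), "degenerate")
  expect_error(pearson(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("observed cohort reproduces the published correlations and t-test", {
  cohort <- fixture_cohort()
  expect_equal(nrow(cohort), 33)
  report <- suppressMessages(run_study_analysis(cohort))
  # UC: 7 patients x 3 phases = 21 pooled (PMS, RHI) pairs
  uc <- report$correlations$UC$two_tailed
  expect_equal(uc$n, 21)
  expect_equal(round(uc$r, 3), 0.751)
  expect_lt(uc$p_value, 0.01)
  # CD: 4 patients x 3 phases = 12 pooled (HBI, RHI) pairs
  cd <- report$correlations$CD
  expect_equal(cd$two_tailed$n, 12)
  expect_equal(round(cd$two_tailed$r, 3), 0.651)
  # the published 0.011 corresponds to the one-tailed test
  expect_equal(cd$one_tailed$p_value, 0.011, tolerance = 0.02)
  expect_equal(cd$two_tailed$p_value, 0.022, tolerance = 0.02)
  # RHI improves from t0 to t2: t ~ 5.61, df 10, p < 0.001
  tt <- report$paired_tests$rhi
  expect_equal(tt$statistic, 5.606, tolerance = 1e-3)
  expect_equal(tt$df, 10)
  expect_lt(tt$p_value, 0.001)
  expect_equal(tt$p_value, 2.258e-4, tolerance = 1e-3)
})

test_that("correlation pooling matches a direct per-disease computation", {
  report <- suppressMessages(run_study_analysis(fixture_cohort()))
  uc_ids <- names(observed_pms)
  r_uc <- naive_pearson(unlist(observed_pms),
                        unlist(observed_rhi[uc_ids]))
  cd_ids <- names(observed_hbi)
  r_cd <- naive_pearson(unlist(observed_hbi),
                        unlist(observed_rhi[cd_ids]))
  expect_equal(report$correlations$UC$two_tailed$r, r_uc, tolerance = 1e-12)
  expect_equal(report$correlations$CD$two_tailed$r, r_cd, tolerance = 1e-12)
})

test_that("cohort validation enforces the record contract", {
  cohort <- fixture_cohort()
  expect_error(run_study_analysis(cohort[0, ]), "empty")
  bad <- cohort; bad$disease[1] <- "XX"
  expect_error(validate_cohort(bad), "disease")
  bad <- cohort; bad$phase[1] <- "t3"
  expect_error(validate_cohort(bad), "phase")
  bad <- cohort; bad$rhi[1] <- -2
  expect_error(validate_cohort(bad), ">= 0")
  bad <- cohort; bad$phase[2] <- "t0"
  expect_error(validate_cohort(bad), "duplicated phase")
  bad <- cohort[, setdiff(names(cohort), "rhi")]
  expect_error(validate_cohort(bad), "missing columns")
})

test_that("full study analysis on a synthetic cohort is well formed", {
  cohort <- generate_cohort(cohort_spec(seed = 123))
  report <- run_study_analysis(cohort)
  expect_named(report, c("summaries", "paired_tests", "correlations"))
  for (ep in c("rhi", "teer", "pm", "roseburia")) {
    expect_false(is.null(report$summaries[[ep]]$t0))
    expect_gte(report$summaries[[ep]]$t0$std, 0)
  }
  for (tt in report$paired_tests) {
    expect_true(tt$p_value >= 0 && tt$p_value <= 1)
  }
  # controls: summaries plus a paired comparison against t0
  ctrl <- data.frame(patient_id = 1:11,
                     teer = rnorm(11, 21.15, 5),
                     pm = abs(rnorm(11, 0.686e-6, 0.3e-6)))
  rep2 <- run_study_analysis(cohort, controls = ctrl)
  expect_false(is.null(rep2$controls$teer$summary))
  expect_false(is.null(rep2$controls$teer$t0_vs_control))
})
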