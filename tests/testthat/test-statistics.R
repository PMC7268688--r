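test_that("identical repeats give ICC 1, unrelated repeats give ICC 0", {
  set.seed(71)
  vals <- matrix(stats::runif(10 * 64, 500, 9000), 10, 64)
  t1 <- make_table(vals, measurement_id = 1L)
  t2 <- make_table(vals, measurement_id = 2L)
  res <- icc(list(t1, t2))
  expect_equal(unname(res$per_region), rep(1, 64))
  expect_equal(res$average, 1)

  # independent draws share nothing: average ICC near 0
  cc1 <- cohort_config(n_subjects = 300, seed = 72)
  cc2 <- cohort_config(n_subjects = 300, seed = 73)
  a <- generate_cohort(cc1)$iBEAT_corrected
  b <- generate_cohort(cc2)$iBEAT_corrected
  b$subject_ids <- a$subject_ids
  rownames(b$values) <- a$subject_ids
  res0 <- icc(list(a, b))
  expect_lt(abs(res0$average), 0.05)
})

test_that("ICC matches the aov mean-squares oracle", {
  set.seed(74)
  for (rep in 1:5) {
    y <- matrix(stats::rnorm(5 * 2, mean = 50, sd = 4), 5, 2)
    y <- y + stats::rnorm(5, sd = 6)  # subject effect
    vals1 <- matrix(stats::runif(5 * 64, 500, 9000), 5, 64)
    vals2 <- vals1
    vals1[, 1] <- y[, 1]
    vals2[, 1] <- y[, 2]
    res <- icc(list(make_table(vals1), make_table(vals2,
                                                  measurement_id = 2L)))
    expect_equal(unname(res$per_region[1]), oracle_icc_aov(y),
                 tolerance = 1e-10)
  }
})

test_that("zero-variance regions are flagged degenerate with ICC 1", {
  vals <- matrix(stats::runif(6 * 64, 500, 9000), 6, 64)
  vals[, 3] <- 1234
  t1 <- make_table(vals)
  t2 <- make_table(vals, measurement_id = 2L)
  res <- icc(list(t1, t2))
  expect_equal(res$degenerate, region_labels()[3])
  expect_equal(unname(res$per_region[3]), 1)
  expect_error(icc(list(t1)), "at least 2")
})

test_that("Bland-Altman reproduces hand-computed limits", {
  res <- bland_altman(c(10, 20, 30, 40), c(12, 19, 31, 38))
  expect_equal(res$mean_diff, 0)
  expect_equal(res$sd_diff, sqrt(10 / 3))
  expect_equal(res$loa_low, -1.96 * sqrt(10 / 3))
  expect_equal(res$loa_high, 1.96 * sqrt(10 / 3))
  expect_equal(res$pct_within, 100)

  exact <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$mean_diff, 0)
  expect_equal(exact$sd_diff, 0)
  expect_equal(c(exact$loa_low, exact$loa_high), c(0, 0))
  expect_equal(exact$pct_within, 100)

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("the 1.96 SD limits capture about 95% of Gaussian differences", {
  set.seed(75)
  x <- stats::rnorm(1e5, 100, 3)
  y <- x + stats::rnorm(1e5, 0, 2)
  res <- bland_altman(x, y)
  expect_lt(abs(res$pct_within - 95), 0.5)
})

test_that("per-region ANOVA matches explicit mean-square arithmetic", {
  set.seed(76)
  base <- matrix(stats::runif(2 * 64, 500, 9000), 2, 64)
  groups <- list(A = base * 1.0, B = base * 1.1, C = base * 0.9)
  tabs <- lapply(names(groups), function(w) {
    vals <- groups[[w]] + matrix(stats::runif(2 * 64, 0, 50), 2, 64)
    volume_table(vals, subject_ids = paste0(w, 1:2), workflow = w)
  })
  names(tabs) <- names(groups)
  res <- anova_per_region(tabs)
  for (r in c(1, 10, 64)) {
    f_oracle <- oracle_anova_f(lapply(names(groups), function(w) {
      tabs[[w]]$values[, r]
    }))
    expect_equal(res$per_region$F[r], f_oracle, tolerance = 1e-10)
  }
})

test_that("identical workflow tables yield F = 0 everywhere", {
  set.seed(77)
  vals <- matrix(stats::runif(8 * 64, 500, 9000), 8, 64)
  tabs <- list(A = make_table(vals, "A"), B = make_table(vals, "B"),
               C = make_table(vals, "C"))
  res <- anova_per_region(tabs)
  expect_equal(res$per_region$F, rep(0, 64))
  expect_equal(res$n_significant, 0L)
})

test_that("a 10-SD mean shift is detected with certainty", {
  labels <- region_labels()
  bias <- stats::setNames(rep(1, 64), labels)
  shift_bias <- bias
  # shift region 5 by ~10 within-group SDs (sd = 12% of mean)
  shift_bias[5] <- 1 + 10 * 0.12
  cc_shift <- cohort_config(
    seed = 78,
    workflow_bias = list(A = bias, B = shift_bias, C = bias))
  cohort <- generate_cohort(cc_shift)
  # groups must be independent draws for a valid F test
  cohort$A <- generate_cohort(cohort_config(
    seed = 79, workflow_bias = list(A = bias)))$A
  cohort$C <- generate_cohort(cohort_config(
    seed = 80, workflow_bias = list(C = bias)))$C
  res <- anova_per_region(cohort[c("A", "B", "C")])
  expect_lt(res$per_region$p[5], 0.05)
  expect_gt(res$per_region$F[5], 10)
})

test_that("BH adjustment never finds more regions than raw p-values", {
  set.seed(81)
  tabs <- generate_cohort(cohort_config(seed = 81))
  raw <- anova_per_region(tabs, adjustment = "none")
  bh <- anova_per_region(tabs, adjustment = "BH")
  expect_lte(bh$n_significant, raw$n_significant)
  expect_true(all(bh$per_region$p_adj >= bh$per_region$p))
})

test_that("identical tables give zero metric differences and p near 1", {
  set.seed(82)
  vals <- matrix(stats::runif(12 * 64, 500, 9000), 12, 64)
  tabs <- list(A = make_table(vals, "A"), B = make_table(vals, "B"))
  res <- compare_network_metrics(tabs, sparsity_range = c(0.2, 0.3),
                                 metrics = "Cp", n_perm = 100, seed = 5)
  expect_equal(res$comparisons$observed_diff, 0)
  expect_equal(res$comparisons$p_value, 1)
  # determinism
  res2 <- compare_network_metrics(tabs, sparsity_range = c(0.2, 0.3),
                                  metrics = "Cp", n_perm = 100, seed = 5)
  expect_identical(res$comparisons, res2$comparisons)
})

test_that("noisier skull stripping lowers network clustering", {
  # subject-varying stripping noise dilutes the modular covariance
  # structure, so the noisy workflow's network is closer to random and its
  # clustering AUC is below the clean workflow's
  cc <- cohort_config(
    seed = 83,
    workflow_noise_sd = c(BET = 0.10, iBEAT = 0, iBEAT_corrected = 0))
  cohort <- generate_cohort(cc)
  tabs <- cohort[c("BET", "iBEAT_corrected")]
  res <- compare_network_metrics(tabs, sparsity_range = c(0.15, 0.25, 0.35),
                                 metrics = "Cp", n_perm = 100, seed = 6)
  expect_lt(res$comparisons$observed_diff, 0)  # BET minus corrected
})

test_that("comparison inputs are validated", {
  set.seed(84)
  vals <- matrix(stats::runif(6 * 64, 500, 9000), 6, 64)
  t1 <- make_table(vals, "A")
  t2 <- volume_table(vals, subject_ids = paste0("other", 1:6),
                     workflow = "B")
  expect_error(compare_network_metrics(list(A = t1, B = t2), n_perm = 100),
               "identical subjects")
  expect_error(compare_network_metrics(list(A = t1, B = t1), n_perm = 50),
               ">= 100")
  small <- make_table(vals[1, , drop = FALSE])
  expect_error(anova_per_region(list(A = small, B = small)),
               "at least 2 subjects")
})
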