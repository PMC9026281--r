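test_that("Spearman handles perfect association and ties", {
  expect_equal(spearman_corr(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_corr(1:3, c(30, 20, 10))$rho, -1)
  # midranks then Pearson by hand: 4.5 / sqrt(22.5)
  tied <- spearman_corr(c(1, 2, 2, 3), c(1, 2, 3, 4))
  expect_equal(round(tied$rho, 4), 0.9487)
  expect_equal(tied$rho, 4.5 / sqrt(22.5), tolerance = 1e-12)
})

test_that("Spearman is symmetric and monotone-invariant", {
  set.seed(51)
  for (i in 1:5) {
    x <- rnorm(12)
    y <- rnorm(12)
    a <- spearman_corr(x, y)
    expect_equal(a$rho, spearman_corr(y, x)$rho, tolerance = 1e-12)
    expect_equal(spearman_corr(exp(x), y)$rho, a$rho, tolerance = 1e-12)
    expect_equal(spearman_corr(x, y^3)$rho, a$rho, tolerance = 1e-12)
  }
})

test_that("Spearman agrees with the base-R estimate and exact p", {
  set.seed(52)
  for (i in 1:5) {
    x <- rnorm(7)
    y <- rnorm(7)
    ours <- spearman_corr(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$method_note, "exact")
  }
  # large-n branch uses the t approximation
  x <- rnorm(40); y <- x + rnorm(40)
  big <- spearman_corr(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(big$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(big$method_note, "approximate")
})

test_that("Spearman rejects unusable inputs and drops incomplete pairs", {
  expect_error(spearman_corr(1:2, 1:2), "insufficient")
  expect_error(spearman_corr(c(1, 1, 1), 1:3), "undefined")
  with_na <- spearman_corr(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(with_na$n_used, 3)
})

test_that("Wilcoxon worked examples match enumeration", {
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$n_effective, 3)
  one <- wilcoxon_signed_rank(5, 0)
  expect_equal(one$statistic, 0)
  expect_equal(one$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate")
})

test_that("exact Wilcoxon p matches an independent enumeration oracle", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(2:12, 1)
    d <- round(rnorm(n, 0.3, 1), 1)  # rounding produces ties and zeros
    if (all(d == 0)) d[1] <- 0.5
    ours <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(ours$p_value, naive_wilcoxon_p(d), tolerance = 1e-12)
    expect_equal(ours$method_note, "exact")
  }
})

test_that("exact Wilcoxon matches wilcox.test when that test is exact", {
  set.seed(54)
  for (i in 1:10) {
    a <- rnorm(9)
    b <- rnorm(9)  # continuous: no ties, no zeros
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon approximation matches base R", {
  set.seed(55)
  a <- rnorm(40, 0.4)
  b <- rnorm(40)
  ours <- wilcoxon_signed_rank(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$method_note, "approximate")
})

test_that("median/IQR summary uses interpolated order statistics", {
  expect_equal(unname(cohort_median_iqr(c(1, 2, 3, 4))["median"]), 2.5)
  set.seed(56)
  x <- rnorm(37)
  q <- cohort_median_iqr(x)
  expect_equal(unname(q["q1"]),
               unname(quantile(x, 0.25, type = 7)), tolerance = 1e-12)
  # permutation invariance and positive-affine equivariance
  expect_equal(cohort_median_iqr(sample(x)), q)
  expect_equal(unname(cohort_median_iqr(2 * x + 5)),
               unname(2 * q + 5), tolerance = 1e-12)
  expect_error(cohort_median_iqr(numeric()), "no finite values")
  alt <- cohort_median_iqr(x, quantile_method = "exclusive")
  expect_equal(unname(alt["q1"]),
               unname(quantile(x, 0.25, type = 6)), tolerance = 1e-12)
})

test_that("reference cohort summary reproduces the published quartiles", {
  ref <- reference_cohort()
  expect_equal(nrow(ref), 21)
  q <- cohort_median_iqr(ref$mean)
  expect_equal(unname(q["median"]), -59.9)
  expect_equal(unname(q["q1"]), -66.3)
})

test_that("the study report assembles all analyses and logs skips", {
  set.seed(57)
  n <- 20
  inf <- runif(n, 0, 90)
  tab <- data.frame(
    subject_id = sprintf("S%02d", 1:n),
    whole_mean = -96 + 1.2 * inf + rnorm(n, 0, 4),
    regional_mean = -96 + 1.2 * inf + rnorm(n, 5, 4),
    lesion_mean = c(rep(NA, 5), runif(n - 5, -20, 30)),
    infiltration_pct = inf,
    haemoglobin = 145 - 0.4 * inf + rnorm(n, 0, 6),
    age = round(runif(n, 40, 85)))
  rep <- run_study_statistics(tab)
  expect_gt(rep$correlations$infiltration_pct$rho, 0.6)
  expect_lt(rep$correlations$haemoglobin$rho, 0)
  expect_equal(rep$comparisons$whole_vs_lesion$n_effective, n - 5)
  expect_true(any(grepl("lesion", rep$log)))  # the NA drops are logged

  # degenerate comparison is skipped with a reason, not a crash
  tab2 <- tab
  tab2$regional_mean <- tab2$whole_mean
  rep2 <- run_study_statistics(tab2)
  expect_null(rep2$comparisons$whole_vs_regional)
  expect_true(any(grepl("regional", rep2$log)))

  expect_error(run_study_statistics(rbind(tab, tab[1, ])), "unique")
})
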