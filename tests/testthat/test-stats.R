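rank_sum_oracle <- function(x, y) {
  r <- rank(c(x, y))
  m <- length(x)
  w <- sum(r[seq_len(m)])
  sums <- apply(utils::combn(length(r), m), 2, function(ix) sum(r[ix]))
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("exact rank-sum test: textbook case and degenerate input", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.1)        # 2 * 1/20, the most extreme split
  expect_equal(res$method, "exact")

  # matches R's exact test when there are no ties
  x <- c(12.1, 15.3, 9.8, 14.2, 11.0, 16.4)
  y <- c(18.9, 13.5, 21.2, 17.7, 19.8, 16.1)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)

  expect_warning(r0 <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)), "tied")
  expect_equal(r0$p_value, 1)
  expect_error(wilcoxon_rank_sum(c(1, NA), c(2, 3)), "missing values")
})

test_that("exact rank-sum test agrees with brute-force enumeration under ties", {
  set.seed(21)
  for (rep in 1:25) {
    x <- sample(1:5, sample(3:5, 1), replace = TRUE)
    y <- sample(1:5, sample(3:5, 1), replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, rank_sum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation engages above n = 25", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15) + 1
  res <- wilcoxon_rank_sum(x, y)
  expect_equal(res$method, "normal-approximation")
  expect_equal(res$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("signed-rank test: extreme case, symmetry, zeros, oracle", {
  # all 18 differences positive: doubled single most-extreme assignment
  res <- wilcoxon_signed_rank(1:18)
  expect_equal(res$statistic, sum(1:18))
  expect_equal(res$p_value, 2 / 2^18)
  expect_equal(res$n_nonzero, 18L)

  # perfectly sign-symmetric differences carry no evidence
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))$p_value, 1)

  # zeros are dropped, not counted
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1:6))$p_value,
               wilcoxon_signed_rank(1:6)$p_value)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1:6))$n_nonzero, 6L)

  # agreement with R's exact test on tie-free differences
  d <- c(2.3, -1.1, 3.8, 0.7, -2.9, 4.4, 1.6, -0.4)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value)

  # flipping a negative difference positive can only raise the statistic
  d1 <- c(1, 2, 3, 4, -5, -6)
  d2 <- c(1, 2, 3, 4, 5, -6)
  expect_gt(wilcoxon_signed_rank(d2)$statistic,
            wilcoxon_signed_rank(d1)$statistic)

  expect_warning(rz <- wilcoxon_signed_rank(c(0, 0, 0)), "all differences zero")
  expect_equal(rz$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4)), "at least 5 non-zero")
  expect_error(wilcoxon_signed_rank(c(NA, 1:6)), "missing values")
})

test_that("spearman correlation: exact permutation and t-approximation", {
  # perfect monotone association at n = 5: only 2 of 5! rank permutations
  # are as extreme
  res <- spearman_rank(1:5, c(10, 20, 30, 40, 50))
  expect_equal(res$rho, 1)
  expect_equal(res$p_value, 2 / factorial(5))
  expect_equal(res$method, "exact-permutation")
  rev <- spearman_rank(1:5, c(50, 40, 30, 20, 10))
  expect_equal(rev$rho, -1)
  expect_equal(rev$p_value, 2 / factorial(5))

  # exact p matches R's exact Spearman test for tie-free n = 7
  set.seed(3)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_rank(x, y)$p_value,
               stats::cor.test(x, y, method = "spearman",
                               exact = TRUE)$p.value)

  # n > 8: rho is the rank correlation, p from the t reference
  x12 <- rnorm(12); y12 <- x12 + rnorm(12)
  r12 <- spearman_rank(x12, y12)
  expect_equal(r12$method, "t-approximation")
  expect_equal(r12$rho, stats::cor(x12, y12, method = "spearman"))

  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rank(1:4, 1:5), "length")
})

test_that("gradient-descent logistic fit matches the converged MLE", {
  set.seed(8)
  w <- c(rnorm(20, 0), rnorm(20, 1.5))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic_gd(w, y)
  expect_true(fit$converged)
  expect_gt(coef(fit)["beta1"], 0)
  z <- (w - mean(w)) / sd(w)
  ref <- stats::glm(y ~ z, family = stats::binomial())
  expect_equal(unname(coef(fit)), unname(stats::coef(ref)), tolerance = 1e-4)
  # predictions live in (0, 1) and increase with the predictor
  p <- predict(fit, sort(w))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(p) >= 0))

  # label flip mirrors the coefficients
  flip <- fit_logistic_gd(w, 1 - y)
  expect_equal(unname(coef(flip)), -unname(coef(fit)), tolerance = 1e-6)

  # perfect separation never converges; given enough iterations the
  # coefficient walk reaches the cap and is flagged
  sep_slow <- suppressWarnings(
    fit_logistic_gd(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)))
  expect_false(sep_slow$converged)
  expect_warning(sep <- fit_logistic_gd(c(1, 2, 3, 4, 5, 6),
                                        c(0, 0, 0, 1, 1, 1),
                                        max_iter = 500000L), "separation")
  expect_true(sep$capped)
  expect_equal(unname(coef(sep)["beta1"]), 30)
  expect_error(fit_logistic_gd(1:5, rep(1, 5)), "both classes")
})

test_that("confusion metrics: definitions and NULL on empty denominators", {
  m <- evaluate_confusion(confusion_counts(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)

  # no positives at all: sensitivity is NULL, never zero
  m0 <- evaluate_confusion(confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_null(m0$sensitivity)
  expect_equal(m0$specificity, 1)
  expect_error(confusion_counts(-1, 0, 0, 0), "tp")
})

test_that("ROC AUC: rank formulation equals trapezoidal integration", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  set.seed(5)
  for (rep in 1:10) {
    scores <- sample(1:6, 20, replace = TRUE)   # heavy ties
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    pts <- r$points
    trap <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("cross-validation is seeded, row-order invariant and stratified", {
  co <- generate_synthetic_cohort(synthetic_cohort_spec(seed = 2))
  cv1 <- cross_validate("stress_2g_ef", co, repeats = 20, seed = 7)
  cv2 <- cross_validate("stress_2g_ef", co, repeats = 20, seed = 7)
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_identical(cv1$per_repeat, cv2$per_repeat)

  shuffled <- co[sample(nrow(co)), ]
  cv3 <- cross_validate("stress_2g_ef", shuffled, repeats = 20, seed = 7)
  expect_equal(cv3$accuracy, cv1$accuracy)
  expect_equal(cv3$auc, cv1$auc)

  cv4 <- cross_validate("stress_2g_ef", co, repeats = 20, seed = 8)
  expect_false(identical(cv1$per_repeat, cv4$per_repeat))

  # 6 + 6 stratified into 5 folds never yields a single-class training set
  expect_equal(cv1$skipped_folds, 0L)
  expect_equal(nrow(cv1$per_repeat), 20L)
  expect_true(all(cv1$per_repeat$accuracy >= 0 & cv1$per_repeat$accuracy <= 1))

  expect_error(cross_validate("no_such_column", co), "unknown predictor")
})
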