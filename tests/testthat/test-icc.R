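# Agreement statistics: ANOVA decomposition, ICC estimates and intervals,
# confusion matrices.

test_that("mean squares match the hand-computed 3x2 table", {
  ms <- anova_mean_squares(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ms$ms_rows, 2)
  expect_equal(ms$ms_cols, 0)
  expect_equal(ms$ms_error, 0)
  expect_identical(c(ms$df_rows, ms$df_cols, ms$df_error), c(2L, 1L, 2L))
})

test_that("a constant matrix has zero mean squares everywhere", {
  ms <- anova_mean_squares(matrix(4.2, 5, 3))
  expect_equal(ms$ms_rows, 0)
  expect_equal(ms$ms_cols, 0)
  expect_equal(ms$ms_error, 0)
})

test_that("sums of squares reconstruct the total and match aov()", {
  set.seed(5)
  m <- random_ratings(6, 4)
  ms <- anova_mean_squares(m)
  ss <- ms$ms_rows * ms$df_rows + ms$ms_cols * ms$df_cols +
    ms$ms_error * ms$df_error
  expect_equal(ss, sum((m - mean(m))^2), tolerance = 1e-9)

  long <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(aov(y ~ subj + rater, data = long))[[1]]
  expect_equal(ms$ms_rows, tab["subj", "Mean Sq"], tolerance = 1e-9)
  expect_equal(ms$ms_cols, tab["rater", "Mean Sq"], tolerance = 1e-9)
  expect_equal(ms$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-9)
})

test_that("matrix validation rejects degenerate input", {
  expect_error(anova_mean_squares(matrix(1, 1, 3)), class = "iqrank_validation_error")
  expect_error(anova_mean_squares(cbind(1:5)), class = "iqrank_validation_error")
  expect_error(anova_mean_squares(cbind(c(1, NA, 3), 1:3)),
               class = "iqrank_validation_error")
  expect_error(icc_agreement(matrix(3, 4, 3)), class = "iqrank_validation_error")
  expect_error(icc_agreement(cbind(1:4, 1:4), alpha = 1.2),
               class = "iqrank_validation_error")
})

test_that("perfect absolute agreement returns exactly 1", {
  m <- cbind(c(1, 2, 3), c(1, 2, 3))
  for (meas in c("single", "average")) {
    res <- icc_agreement(m, meas)
    expect_identical(res$estimate, 1)
    expect_identical(c(res$ci_low, res$ci_high), c(1, 1))
  }
})

test_that("estimates and intervals match the brute-force oracle", {
  set.seed(11)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    k <- sample(2:6, 1)
    m <- random_ratings(n, k)
    for (meas in c("single", "average")) {
      res <- icc_agreement(m, meas)
      ref <- bf_icc(m, meas)
      expect_equal(res$estimate, ref$estimate, tolerance = 1e-9)
      expect_equal(c(res$ci_low, res$ci_high), ref$ci, tolerance = 1e-9)
    }
  }
})

test_that("zero subject variance with rater offsets gives a negative raw ICC", {
  # no subject effect, distinct rater offsets, alternating perturbation whose
  # row means are constant: MSR = 0 < MSE, so the raw estimate is negative
  m <- outer(rep(0, 8), c(0, 2, -2, 1), "+") +
    0.3 * outer((-1)^(1:8), (-1)^(1:4))
  res <- icc_agreement(m, "single")
  expect_lt(res$estimate, 0)
  expect_identical(res$clamped$estimate, 0)
  expect_identical(res$clamped$ci_low, 0)
})

test_that("absolute-agreement ICC is translation and scale invariant", {
  set.seed(7)
  m <- random_ratings(10, 4)
  base <- icc_agreement(m, "single")$estimate
  expect_equal(icc_agreement(m + 11.5, "single")$estimate, base, tolerance = 1e-12)
  expect_equal(icc_agreement(m * 3.7, "single")$estimate, base, tolerance = 1e-12)
  # but shifting one rater's column strictly lowers agreement
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 5
  expect_lt(icc_agreement(shifted, "single")$estimate, base)
  expect_lt(icc_agreement(shifted, "average")$estimate,
            icc_agreement(m, "average")$estimate)
})

test_that("average-measures ICC dominates single-measures when positive", {
  set.seed(13)
  for (r in 1:20) {
    m <- random_ratings(8, 4)
    s <- icc_agreement(m, "single")$estimate
    a <- icc_agreement(m, "average")$estimate
    if (s > 0) expect_gte(a, s)
  }
})

test_that("confusion matrices count score pairs", {
  cm <- confusion_matrix(c(3, 3, 4), c(3, 3, 4))
  expect_identical(cm["3", "3"], 2L)
  expect_identical(cm["4", "4"], 1L)
  expect_identical(sum(cm), 3L)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0L))

  cm2 <- confusion_matrix(2, 5)
  expect_identical(cm2["2", "5"], 1L)
  expect_identical(sum(cm2), 1L)

  set.seed(4)
  a <- sample(1:5, 40, replace = TRUE)
  b <- sample(1:5, 40, replace = TRUE)
  cm3 <- confusion_matrix(a, b)
  expect_identical(as.integer(rowSums(cm3)), unname(tabulate(a, 5)))
  expect_identical(sum(cm3), 40L)

  expect_error(confusion_matrix(1:3, 1:2), class = "iqrank_validation_error")
  expect_error(confusion_matrix(c(1, 6), c(1, 2)), class = "iqrank_validation_error")
})

test_that("ratings CSV round-trips through the subject_id layout", {
  m <- ratings_matrix(cbind(c(1, 2, 3), c(2, 2, 4)),
                      subject_ids = c("s1", "s2", "s3"),
                      rater_ids = c("obsA", "obsB"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(m, path)
  head <- readLines(path, n = 1)
  expect_identical(head, "subject_id,obsA,obsB")
  m2 <- read_ratings_csv(path)
  expect_equal(unname(m2), unname(m))
  expect_identical(dimnames(m2), dimnames(m))
})
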