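# Agreement statistics: two-way random-effects, absolute-agreement
# intraclass correlation coefficients (single and average measures) with
# F-based 95% confidence intervals, plus Likert confusion matrices.
#
# Estimators follow the variance-component conventions of McGraw & Wong
# (ICC(A,1) and ICC(A,k)), the parameterization implemented by mainstream
# statistical packages, so results line up with SPSS "two-way random,
# absolute agreement" output for the same matrix.

#' Construct a ratings matrix
#'
#' A complete subjects-by-raters score table (ranks or Likert scores). The
#' design must be complete: no missing cells, at least 2 subjects and 2
#' raters. Missing data are rejected rather than imputed, since silent
#' imputation would change the estimand.
#'
#' @param values Numeric matrix (or object coercible to one), subjects in
#'   rows, raters in columns.
#' @param subject_ids Optional row labels (default `S1..Sn`).
#' @param rater_ids Optional column labels (default `R1..Rk`).
#' @return A numeric matrix with dimnames set.
#' @export
ratings_matrix <- function(values, subject_ids = NULL, rater_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    validation_error("a ratings matrix needs at least 2 subjects and 2 raters")
  }
  if (any(!is.finite(m))) {
    validation_error(paste0(
      "ratings matrix contains missing or non-finite cells; ",
      "complete cases must be resolved upstream (no imputation is performed)"
    ))
  }
  rownames(m) <- if (is.null(subject_ids)) sprintf("S%d", seq_len(nrow(m))) else as.character(subject_ids)
  colnames(m) <- if (is.null(rater_ids)) sprintf("R%d", seq_len(ncol(m))) else as.character(rater_ids)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    validation_error("subject and rater labels must be distinct")
  }
  m
}

check_ratings <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L) {
    validation_error("a ratings matrix needs at least 2 subjects and 2 raters")
  }
  if (any(!is.finite(m))) {
    validation_error(paste0(
      "ratings matrix contains missing or non-finite cells; ",
      "complete cases must be resolved upstream (no imputation is performed)"
    ))
  }
  m
}

#' Two-way ANOVA mean squares of a ratings matrix
#'
#' Crossed subjects-by-raters decomposition: `SS_total = SS_rows + SS_cols +
#' SS_error` with degrees of freedom `n-1`, `k-1` and `(n-1)(k-1)`. These
#' mean squares are the sufficient statistics for every agreement ICC in the
#' package.
#'
#' @param m Ratings matrix (see [ratings_matrix()]).
#' @return A list with `ms_rows`, `ms_cols`, `ms_error`, `df_rows`,
#'   `df_cols`, `df_error`, `n`, `k`.
#' @export
#' @examples
#' anova_mean_squares(ratings_matrix(cbind(1:3, 1:3)))
anova_mean_squares <- function(m) {
  m <- check_ratings(m)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  df_rows <- n - 1L
  df_cols <- k - 1L
  df_error <- df_rows * df_cols
  list(
    ms_rows = ss_rows / df_rows,
    ms_cols = ss_cols / df_cols,
    ms_error = ss_error / df_error,
    df_rows = df_rows,
    df_cols = df_cols,
    df_error = df_error,
    n = n,
    k = k
  )
}

#' Absolute-agreement intraclass correlation coefficient
#'
#' Two-way random-effects ICC for absolute agreement. `measures = "single"`
#' (the reliability of one rater; used for intraobserver agreement over
#' repeated sessions) estimates
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`;
#' `measures = "average"` (the reliability of the k-rater mean; used for
#' interobserver agreement) estimates
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)`.
#'
#' Confidence intervals use the F-based method for the two-way random
#' absolute-agreement model: the single-measures interval uses a
#' Satterthwaite-approximated denominator df, and the average-measures
#' interval is obtained from it by the Spearman-Brown step — the convention
#' of mainstream statistical software, so printed SPSS tables are
#' reproducible from the same matrix. Raw estimates may be negative;
#' `clamped` floors the estimate and both bounds at 0 for report tables.
#'
#' @param m Ratings matrix, subjects in rows, raters in columns.
#' @param measures `"single"` or `"average"`.
#' @param alpha Significance level for the `1 - alpha` confidence interval
#'   (default 0.05).
#' @return An `icc_result`: `estimate`, `ci_low`, `ci_high`, `measures`,
#'   `model`, mean squares and df, `alpha`, `n`, `k`, and `clamped`
#'   (estimate and CI floored at 0).
#' @export
#' @examples
#' m <- ratings_matrix(cbind(c(1, 2, 3, 4), c(2, 3, 3, 5)))
#' icc_agreement(m, "average")
icc_agreement <- function(m, measures = c("single", "average"), alpha = 0.05) {
  measures <- match.arg(measures)
  if (length(alpha) != 1L || !is.numeric(alpha) || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    validation_error("`alpha` must be a probability strictly between 0 and 1")
  }
  ms <- anova_mean_squares(m)
  msr <- ms$ms_rows
  msc <- ms$ms_cols
  mse <- ms$ms_error
  n <- ms$n
  k <- ms$k

  if (msr <= 0 && mse <= 0) {
    validation_error(paste0(
      "ICC is undefined for a constant matrix: both the subject and the ",
      "residual mean squares are zero, so there is no variance to apportion"
    ))
  }

  if (mse == 0 && msc == 0) {
    # Raters agree perfectly and identically on varying subjects: the
    # estimate is exactly 1 and both F-interval bounds have limit 1.
    est <- 1
    ci <- c(1, 1)
  } else {
    est_single <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    a <- (k * est_single) / (n * (1 - est_single))
    b <- 1 + (k * est_single * (n - 1)) / (n * (1 - est_single))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    if (!is.finite(v) || v <= 0) {
      # msr = 0 makes a*msc + b*mse cancel exactly, degenerating the
      # Satterthwaite df; both F-interval limits then collapse onto the
      # point estimate.
      low1 <- est_single
      up1 <- est_single
    } else {
      fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
      fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
      low1 <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      up1 <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
    }
    if (measures == "single") {
      est <- est_single
      ci <- c(low1, up1)
    } else {
      est <- (msr - mse) / (msr + (msc - mse) / n)
      sb <- function(x) x * k / (1 + (k - 1) * x)
      ci <- c(sb(low1), sb(up1))
    }
  }

  structure(
    list(
      estimate = est,
      ci_low = ci[1],
      ci_high = ci[2],
      measures = measures,
      model = "two-way random, absolute agreement",
      ms_rows = msr,
      ms_cols = msc,
      ms_error = mse,
      df_rows = ms$df_rows,
      df_cols = ms$df_cols,
      df_error = ms$df_error,
      alpha = alpha,
      n = n,
      k = k,
      clamped = list(
        estimate = max(0, est),
        ci_low = max(0, ci[1]),
        ci_high = max(0, ci[2])
      )
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "ICC (%s measures, %s): %.*f (%d%%CI %.*f to %.*f)\n",
    x$measures, x$model, digits, x$estimate,
    round(100 * (1 - x$alpha)), digits, x$ci_low, digits, x$ci_high
  ))
  cat(sprintf("  n = %d subjects, k = %d raters\n", x$n, x$k))
  invisible(x)
}

#' Confusion matrix of two score vectors
#'
#' Cross-tabulates two observers' Likert scores (or one observer's two
#' sessions) over the same subjects. Cell (i, j) counts subjects scored
#' `levels[i]` by `a` and `levels[j]` by `b`; a diagonal matrix indicates
#' perfect agreement.
#'
#' @param a,b Integer score vectors of equal length.
#' @param levels Ordered score levels (default `1:5`).
#' @return A `length(levels)` square integer matrix of counts.
#' @export
#' @examples
#' confusion_matrix(c(3, 3, 4), c(3, 3, 4))
confusion_matrix <- function(a, b, levels = 1:5) {
  if (length(a) != length(b)) {
    validation_error("score vectors must have equal length")
  }
  if (!all(a %in% levels) || !all(b %in% levels)) {
    validation_error(sprintf(
      "scores outside the allowed levels {%s}", paste(levels, collapse = ", ")
    ))
  }
  tab <- table(
    factor(a, levels = levels),
    factor(b, levels = levels)
  )
  out <- matrix(as.integer(tab), nrow = length(levels),
                dimnames = list(a = as.character(levels), b = as.character(levels)))
  out
}

#' Read a ratings matrix from CSV
#'
#' Expects the layout `subject_id, <rater 1>, <rater 2>, ...` with a header
#' row of rater identifiers.
#'
#' @param path CSV file path.
#' @return A ratings matrix.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    validation_error("ratings CSV needs a subject_id column plus >= 2 rater columns")
  }
  ratings_matrix(as.matrix(df[, -1, drop = FALSE]),
                 subject_ids = df[[1]],
                 rater_ids = colnames(df)[-1])
}

#' Write a ratings matrix to CSV
#'
#' @param m Ratings matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(m, path) {
  m <- check_ratings(m)
  df <- data.frame(subject_id = rownames(m), m,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
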