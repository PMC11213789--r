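# Shared fixtures and independent oracles, coded separately from the
# package's own computation paths.

# Truthful comparison oracle over a named latent-quality vector.
truthful_oracle <- function(quality) {
  force(quality)
  function(left, right) if (quality[[left]] > quality[[right]]) left else right
}

# All permutations of 1..n (plain recursive enumeration).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[p])
    }
  }
  out
}

# Count of comparisons used by fj_rank for one permutation of true qualities.
fj_comparisons <- function(ids, quality, seed = 1L) {
  nrow(fj_rank(ids, truthful_oracle(quality), seed = seed)$records)
}

# Independent two-way ANOVA sums of squares: explicit elementwise loops, no
# shared code with anova_mean_squares().
bf_mean_squares <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  rmean <- numeric(n)
  for (i in seq_len(n)) rmean[i] <- sum(m[i, ]) / k
  cmean <- numeric(k)
  for (j in seq_len(k)) cmean[j] <- sum(m[, j]) / n
  ss_err <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_err <- ss_err + (m[i, j] - rmean[i] - cmean[j] + grand)^2
    }
  }
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (rmean[i] - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (cmean[j] - grand)^2
  list(
    msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
    mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k
  )
}

# Independent absolute-agreement ICC (estimate + F-based CI), recoded from
# the variance-component definitions.
bf_icc <- function(m, measures, alpha = 0.05) {
  s <- bf_mean_squares(m)
  n <- s$n
  k <- s$k
  est1 <- (s$msr - s$mse) /
    (s$msr + (k - 1) * s$mse + (k / n) * (s$msc - s$mse))
  a <- k * est1 / (n * (1 - est1))
  b <- 1 + k * est1 * (n - 1) / (n * (1 - est1))
  v <- (a * s$msc + b * s$mse)^2 /
    ((a * s$msc)^2 / (k - 1) + (b * s$mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (s$msr - fl * s$mse) /
    (fl * (k * s$msc + (k * n - k - n) * s$mse) + n * s$msr)
  hi1 <- n * (fu * s$msr - s$mse) /
    (k * s$msc + (k * n - k - n) * s$mse + n * fu * s$msr)
  if (measures == "single") {
    list(estimate = est1, ci = c(lo1, hi1))
  } else {
    sb <- function(x) x * k / (1 + (k - 1) * x)
    list(estimate = (s$msr - s$mse) / (s$msr + (s$msc - s$mse) / n),
         ci = c(sb(lo1), sb(hi1)))
  }
}

# Random two-way-model ratings matrix.
random_ratings <- function(n, k, sd_subject = 2, sd_rater = 1, sd_error = 1) {
  outer(rnorm(n, 0, sd_subject), rnorm(k, 0, sd_rater), "+") +
    matrix(rnorm(n * k, 0, sd_error), n, k)
}

# A small, fast study configuration for pipeline tests.
small_study_config <- function(master_seed = 1L, k = 3L,
                               sigma_compare = 0.5, sigma_likert = 0.5) {
  study_config(
    n_patients = 10L, n_excluded = 2L,
    observers = default_observers(k, sigma_compare = sigma_compare,
                                  sigma_likert = sigma_likert),
    master_seed = master_seed
  )
}
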