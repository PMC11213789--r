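# Study pipeline: matrices, determinism, noiseless and null behavior.

test_that("noiseless observers agree perfectly on PC ranks", {
  cfg <- study_config(
    n_patients = 10, n_excluded = 2,
    observers = default_observers(3, sigma_compare = 0, sigma_likert = 0),
    master_seed = 5
  )
  res <- run_study(cfg)
  for (d in c("high", "low")) {
    expect_identical(res$inter_icc[[d]]$pc$estimate, 1)
  }
})

test_that("the study is bit-identical under the same master seed", {
  r1 <- run_study(small_study_config(master_seed = 11))
  r2 <- run_study(small_study_config(master_seed = 11))
  expect_identical(r1$icc_table, r2$icc_table)
  expect_identical(r1$matrices, r2$matrices)
  expect_identical(r1$sessions$pc$high$obs1$records,
                   r2$sessions$pc$high$obs1$records)
  r3 <- run_study(small_study_config(master_seed = 12))
  expect_false(identical(r1$icc_table$estimate, r3$icc_table$estimate))
})

test_that("matrices have the design shapes and shared scan sets", {
  res <- run_study(study_config(master_seed = 3))
  k <- length(res$config$observers)
  for (d in c("high", "low")) {
    expect_identical(dim(res$matrices$inter[[d]]$pc), c(50L, k))
    expect_identical(dim(res$matrices$inter[[d]]$likert), c(50L, k))
    # PC and Likert passes scored the identical 50 scans
    expect_setequal(rownames(res$matrices$inter[[d]]$pc),
                    res$datasets[[d]]$scan_id)
    expect_setequal(rownames(res$matrices$inter[[d]]$likert),
                    res$datasets[[d]]$scan_id)
    # each PC column is a complete ranking 1..50
    expect_true(all(apply(res$matrices$inter[[d]]$pc, 2, sort) == 1:50))
  }
  expect_identical(length(res$originals), 25L)
  for (o in names(res$config$observers)) {
    expect_identical(dim(res$matrices$intra[[o]]$pc), c(25L, 2L))
    expect_identical(dim(res$matrices$intra[[o]]$likert), c(25L, 2L))
  }
})

test_that("interobserver_matrix aligns observers and flags mismatches", {
  a <- setNames(1:3, c("x", "y", "z"))
  b <- setNames(c(2, 1, 3), c("y", "x", "z"))
  m <- interobserver_matrix(list(o1 = a, o2 = b))
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(m["x", "o2"], 1)

  identical_obs <- interobserver_matrix(list(o1 = a, o2 = a))
  expect_identical(identical_obs[, 1], identical_obs[, 2])

  bad <- setNames(1:3, c("x", "y", "w"))
  err <- tryCatch(interobserver_matrix(list(o1 = a, o2 = bad)),
                  iqrank_alignment_error = identity)
  expect_s3_class(err, "iqrank_alignment_error")
  expect_match(conditionMessage(err), "w")
  expect_match(conditionMessage(err), "z")
})

test_that("intraobserver_matrix pairs sessions over the originals", {
  s1 <- setNames(1:4, c("a", "b", "c", "d"))
  s2 <- setNames(c(2, 1, 4, 3), c("a", "b", "c", "d"))
  m <- intraobserver_matrix(s1, s2, c("a", "b", "c"))
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(colnames(m), c("session1", "session2"))

  perfect <- icc_agreement(intraobserver_matrix(s1, s1, names(s1)), "single")
  expect_identical(perfect$estimate, 1)

  expect_error(intraobserver_matrix(s1, s2, c("a", "q")),
               class = "iqrank_alignment_error")
})

test_that("independent sessions give near-zero intraobserver ICC", {
  set.seed(31)
  est <- vapply(1:500, function(r) {
    m <- cbind(sample(50, 25), sample(50, 25))
    icc_agreement(m, "single")$estimate
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.05)
})

test_that("more observer noise never helps interobserver agreement", {
  grid <- c(0.2, 1, 4)
  mean_icc <- vapply(grid, function(sig) {
    mean(vapply(1:30, function(r) {
      res <- run_study(small_study_config(master_seed = 4000 + r,
                                          sigma_compare = sig,
                                          sigma_likert = sig))
      res$inter_icc$high$pc$estimate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_icc) < 0))
})

test_that("study config validation", {
  expect_error(study_config(n_patients = 4, n_excluded = 3),
               class = "iqrank_validation_error")
  expect_error(study_config(observers = list(observer_model())),
               class = "iqrank_validation_error")
  expect_error(study_config(dataset_order = c("high", "high")),
               class = "iqrank_validation_error")
})

test_that("study configs load from JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "n_patients": 12, "n_excluded": 2, "master_seed": 99,
    "quality_model": {"beta_current": 3, "sigma_patient": 0.2},
    "observers": [
      {"scale": 1, "bias": -0.5, "sigma_compare": 0.3},
      {"scale": 1.1, "bias": 0.5, "sigma_compare": 0.3}
    ]
  }', path)
  cfg <- read_study_config(path)
  expect_identical(cfg$n_patients, 12L)
  expect_identical(length(cfg$observers), 2L)
  expect_identical(cfg$observers[[2]]$bias, 0.5)
  expect_identical(cfg$quality_model$beta_current, 3)
  res <- run_study(cfg)
  expect_identical(nrow(res$datasets$high), 20L)
})
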