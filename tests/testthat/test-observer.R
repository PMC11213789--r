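# Synthetic pools, dataset composition and Thurstonian observers.

test_that("30 patients yield 510 scans, 17 each, one original apiece", {
  pool <- generate_scan_pool(30, latent_quality_model())
  expect_identical(nrow(pool), 510L)
  expect_true(all(table(pool$patient_id) == 17))
  orig <- pool[pool$is_original, ]
  expect_identical(nrow(orig), 30L)
  expect_true(all(orig$current_pct == 100 & orig$recon == "IR2"))
  expect_false(any(duplicated(pool$scan_id)))
  # non-originals cover the full 4x4 variant grid per patient
  v <- pool[!pool$is_original & pool$patient_id == "P001", ]
  expect_identical(nrow(v), 16L)
  expect_identical(sort(unique(v$current_pct)), c(60L, 70L, 80L, 90L))
  expect_setequal(unique(v$recon), c("FBP", "IR2", "IR3", "IR4"))
})

test_that("a flat degenerate model gives identical latent qualities", {
  model <- latent_quality_model(beta_current = 0,
                                beta_recon = c(FBP = 0, IR2 = 0, IR3 = 0, IR4 = 0),
                                sigma_patient = 0)
  pool <- generate_scan_pool(1, model)
  expect_identical(nrow(pool), 17L)
  expect_true(all(pool$latent_q == pool$latent_q[1]))
})

test_that("latent quality increases with tube current within patient/recon", {
  pool <- generate_scan_pool(3, latent_quality_model(beta_current = 10))
  for (p in unique(pool$patient_id)) {
    for (rc in c("FBP", "IR2", "IR3", "IR4")) {
      sub <- pool[pool$patient_id == p & pool$recon == rc, ]
      sub <- sub[order(sub$current_pct), ]
      expect_true(all(diff(sub$latent_q) > 0))
    }
  }
})

test_that("pool generation is deterministic in the model seed", {
  p1 <- generate_scan_pool(5, latent_quality_model(seed = 42))
  p2 <- generate_scan_pool(5, latent_quality_model(seed = 42))
  p3 <- generate_scan_pool(5, latent_quality_model(seed = 43))
  expect_identical(p1, p2)
  expect_false(identical(p1$latent_q, p3$latent_q))
})

test_that("composed datasets hold 25 originals plus one variant per patient", {
  pool <- generate_scan_pool(30, latent_quality_model())
  for (prof in c("high", "low")) {
    ds <- compose_dataset(pool, prof, 25, seed = 9)
    expect_identical(nrow(ds), 50L)
    expect_identical(sum(ds$is_original), 25L)
    expect_true(all(table(ds$patient_id[!ds$is_original]) == 1))
    expect_true(all(table(ds$patient_id) == 2))
  }
})

test_that("high-profile cell counts follow the composition table", {
  pool <- generate_scan_pool(30, latent_quality_model())
  ds <- compose_dataset(pool, "high", 25, seed = 4)
  extras <- ds[!ds$is_original, ]
  got <- table(factor(extras$recon, c("FBP", "IR2", "IR3", "IR4")),
               factor(extras$current_pct, c(60, 70, 80, 90)))
  expect_identical(matrix(as.integer(got), 4, 4,
                          dimnames = dimnames(variation_profile("high"))),
                   variation_profile("high"))
})

test_that("composition is deterministic in the seed and minimal cases work", {
  pool <- generate_scan_pool(28, latent_quality_model())
  d1 <- compose_dataset(pool, "low", 25, seed = 7)
  d2 <- compose_dataset(pool, "low", 25, seed = 7)
  expect_identical(d1$scan_id, d2$scan_id)

  one <- compose_dataset(pool, "high", 1, seed = 2)
  expect_identical(nrow(one), 2L)
  expect_identical(length(unique(one$patient_id)), 1L)
  expect_identical(sum(one$is_original), 1L)

  expect_error(compose_dataset(pool[1:30, ], "high", 25, seed = 1),
               class = "iqrank_composition_error")
})

test_that("noiseless choices pick the truly better scan", {
  obs <- observer_model(sigma_compare = 0)
  stream <- rng_stream(1)
  left <- list(scan_id = "L", latent_q = 2)
  right <- list(scan_id = "R", latent_q = 1)
  expect_identical(simulate_choice(obs, left, right, stream), "L")
  expect_identical(simulate_choice(obs, right, left, stream), "L")
})

test_that("equal qualities are chosen at rate 1/2 under noise", {
  obs <- observer_model(sigma_compare = 1)
  stream <- rng_stream(77)
  a <- list(scan_id = "A", latent_q = 0)
  b <- list(scan_id = "B", latent_q = 0)
  hits <- sum(vapply(1:10000, function(i) {
    simulate_choice(obs, a, b, stream) == "A"
  }, logical(1)))
  expect_equal(hits / 10000, 0.5, tolerance = 0.02)
})

test_that("choice probabilities follow the Thurstone Case V probit", {
  # P(left) = pnorm(scale * dq / (sqrt(2) * sigma)); dq = 1, scale = sigma = 1
  obs <- observer_model(scale = 1, sigma_compare = 1)
  stream <- rng_stream(123)
  l <- list(scan_id = "L", latent_q = 1)
  r <- list(scan_id = "R", latent_q = 0)
  n <- 30000
  hits <- sum(vapply(seq_len(n), function(i) {
    simulate_choice(obs, l, r, stream) == "L"
  }, logical(1)))
  expect_equal(hits / n, pnorm(1 / sqrt(2)), tolerance = 0.01)
})

test_that("noiseless Likert scoring respects floor, ceiling and thresholds", {
  obs <- observer_model(sigma_likert = 0, thresholds = c(-2, -1, 1, 2))
  stream <- rng_stream(1)
  expect_identical(simulate_likert(obs, list(latent_q = -5), stream), 1L)
  expect_identical(simulate_likert(obs, list(latent_q = 5), stream), 5L)
  expect_identical(simulate_likert(obs, list(latent_q = 0), stream), 3L)
  expect_identical(simulate_likert(obs, list(latent_q = 1.5), stream), 4L)
})

test_that("Likert cell probabilities match the ordinal-probit closed form", {
  obs <- observer_model(scale = 1, bias = 0, sigma_likert = 1,
                        thresholds = c(-2, -1, 1, 2))
  stream <- rng_stream(55)
  n <- 30000
  scores <- vapply(seq_len(n), function(i) {
    simulate_likert(obs, list(latent_q = 0), stream)
  }, integer(1))
  expect_equal(mean(scores == 3), pnorm(1) - pnorm(-1), tolerance = 0.01)
})

test_that("ranking fidelity degrades monotonically with comparison noise", {
  ids <- sprintf("s%02d", 1:20)
  quality <- setNames(seq(0, 4, length.out = 20), ids)
  ds <- data.frame(scan_id = ids, latent_q = unname(quality))
  mean_rho <- vapply(c(0.05, 0.5, 2.5), function(sig) {
    obs <- observer_model(sigma_compare = sig)
    mean(vapply(1:100, function(r) {
      res <- fj_rank(ids, observer_oracle(obs, ds, seed = 1000 + r), seed = r)
      cor(res$ranking$rank_of[ids], rank(quality), method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_rho[1], 0.99)
  expect_true(all(diff(mean_rho) < 0))
})

test_that("observer and quality-model validation catches bad parameters", {
  expect_error(observer_model(thresholds = c(1, 1, 2, 3)),
               class = "iqrank_validation_error")
  expect_error(observer_model(sigma_compare = -1),
               class = "iqrank_validation_error")
  expect_error(latent_quality_model(beta_current = -2),
               class = "iqrank_validation_error")
  expect_error(latent_quality_model(beta_recon = c(A = 1)),
               class = "iqrank_validation_error")
  expect_error(generate_scan_pool(0), class = "iqrank_validation_error")
})

test_that("scan pool CSV round-trips", {
  pool <- generate_scan_pool(2, latent_quality_model())
  path <- withr::local_tempfile(fileext = ".csv")
  write_scan_pool(pool, path)
  back <- read_scan_pool(path)
  expect_equal(back, pool)
})
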