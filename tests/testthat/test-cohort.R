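test_that("cohort generation is deterministic under spec + seed", {
  a <- generate_cohort(cohort_spec(n_subjects = 20, seed = 42), tacs = TRUE)
  b <- generate_cohort(cohort_spec(n_subjects = 20, seed = 42), tacs = TRUE)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truths, b$truths)
  expect_identical(
    a$tacs[[5]]$ded$cortex$activity,
    b$tacs[[5]]$ded$cortex$activity
  )
  c <- generate_cohort(cohort_spec(n_subjects = 20, seed = 43), tacs = FALSE)
  expect_false(identical(a$cohort$age, c$cohort$age))
})

test_that("spec validation rejects degenerate inputs", {
  expect_error(cohort_spec(n_subjects = 0), ">= 2")
  expect_error(cohort_spec(noise_scale = -1), ">= 0")
  badR <- default_construct_correlations()
  badR[1, 2] <- 0.5 # asymmetric
  expect_error(cohort_spec(correlations = badR))
})

test_that("nearest_psd projects mildly indefinite matrices and rejects others", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- 0.45 # slightly indefinite
  P <- nearest_psd(R)
  expect_true(min(eigen(P, symmetric = TRUE)$values) >= 0)
  expect_equal(diag(P), rep(1, 3))
  expect_lt(max(abs(P - R)), 0.1)
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(nearest_psd(bad), "tolerance")
  psd <- diag(2)
  expect_identical(nearest_psd(psd), psd)
})

test_that("cohort moments match the calibration targets at n = 10,000", {
  spec <- cohort_spec(n_subjects = 10000, seed = 101)
  sim <- generate_cohort(spec, tacs = FALSE)
  co <- sim$cohort
  tr <- sim$truths
  expect_equal(mean(co$age), 67.4, tolerance = 0.03 * 67.4 / 67.4) # 3%
  expect_lt(abs(stats::sd(co$age) - 5.1) / 5.1, 0.03)
  expect_lt(abs(mean(tr$bp_caudate) - 2.24) / 2.24, 0.02)
  expect_lt(abs(mean(tr$bp_putamen) - 3.31) / 3.31, 0.02)
  expect_lt(abs(stats::sd(tr$bp_caudate) - 0.52) / 0.52, 0.03)
  expect_lt(abs(mean(tr$ki_putamen) - 0.07) / 0.07, 0.03)
  expect_lt(abs(mean(tr$ki_cortex) - 0.04) / 0.04, 0.03)
  expect_lt(abs(mean(co$lesion_ml) - 2.0) / 2.0, 0.03)
  expect_lt(abs(stats::sd(co$lesion_ml) - 2.9) / 2.9, 0.10) # heavy tail
  expect_lt(abs(mean(co$sex == "male") - 0.5), 0.02)

  # construct-level correlation structure within +/- 0.03 of the targets
  d <- co
  d$dat_z <- dat_composite(tr$bp_caudate, tr$bp_putamen)
  d$maob_factor <- maob_pca_score(tr[, c("ki_cortex", "ki_hippocampus",
                                         "ki_thalamus")])$scores
  d$log_lesion <- log(d$lesion_ml)
  targets <- default_construct_correlations()
  expect_lt(abs(stats::cor(d$age, d$maob_factor) - targets["age", "maob"]), 0.03)
  expect_lt(abs(stats::cor(d$age, d$log_lesion) - targets["age", "lesion"]), 0.03)
  expect_lt(abs(stats::cor(d$dat_z, d$maob_factor) - targets["dat", "maob"]), 0.03)
  expect_lt(abs(stats::cor(d$dat_z, d$log_lesion) - targets["dat", "lesion"]), 0.03)

  # men carry the higher DAT composite
  gap <- mean(d$dat_z[d$sex == "male"]) - mean(d$dat_z[d$sex == "female"])
  expect_gt(gap, 0.4)

  # score-range invariants
  specs <- cognitive_test_specs()
  for (i in which(specs$type == "accuracy")) {
    v <- co[[specs$test[i]]]
    expect_true(all(v >= 0 & v <= specs$max_score[i]))
  }
  for (te in specs$test[specs$type == "speed"]) {
    expect_true(all(co[[paste0(te, "_correct")]] >= 0))
    expect_true(all(co[[paste0(te, "_rt_ms")]] > 0))
  }
  expect_true(all(co$fazekas %in% 0:3))
  expect_true(all(co$lesion_ml > 0))
})

test_that("identity construct correlations give independent constructs", {
  R <- diag(7)
  dimnames(R) <- dimnames(default_construct_correlations())
  sim <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 5,
                                     correlations = R), tacs = FALSE)
  tr <- sim$truths
  co <- sim$cohort
  vars <- cbind(co$age, co$bmi, tr$latent_dat, tr$latent_maob,
                log(co$lesion_ml), tr$latent_cognition)
  C <- stats::cor(vars)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("an injected extreme lesion volume is flagged by the outlier rule", {
  spec <- cohort_spec(n_subjects = 54, seed = 9,
                      inject_extreme_lesion_ml = 14.7)
  co <- generate_cohort(spec, tacs = FALSE)$cohort
  expect_equal(max(co$lesion_ml), 14.7)
  rep <- univariate_outliers(co$lesion_ml, variable = "lesion_ml")
  expect_true(which.max(co$lesion_ml) %in% rep$flagged)
})

test_that("missingness emulation reproduces the battery's structure", {
  spec <- cohort_spec(n_subjects = 55, seed = 12, emulate_missingness = TRUE)
  sim <- generate_cohort(spec, tacs = TRUE)
  co <- sim$cohort
  # first 10 subjects: episodic only
  expect_true(all(is.na(co$letter_updating[1:10])))
  expect_false(any(is.na(co$word_recall[1:10])))
  # subject 11: working memory only
  expect_true(is.na(co$word_recall[11]))
  expect_false(is.na(co$number_3back[11]))
  # 4 subjects lack the DAT scan
  n_missing_pe2i <- sum(vapply(sim$tacs, function(b) is.null(b$pe2i), TRUE))
  expect_equal(n_missing_pe2i, 4L)
})
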