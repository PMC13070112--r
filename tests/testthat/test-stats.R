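test_that("univariate outlier rule flags the documented worked example", {
  # published lesion summary: mean 2.0 ml, SD 2.9 ml, range 0.1-14.7;
  # only the maximum exceeds the 3.29-SD cut (2.0 + 3.29 x 2.9 = 11.5 ml)
  volumes <- c(seq(0.1, 9.5, length.out = 53), 14.7)
  rep <- univariate_outliers(volumes, center = 2.0, scale = 2.9,
                             variable = "lesion_ml")
  expect_equal(rep$n_flagged, 1L)
  expect_equal(rep$flagged, 54L)
  expect_equal(rep$z[54], (14.7 - 2.0) / 2.9) # 4.38
  expect_gt(rep$z[54], 3.29)
})

test_that("univariate rule handles constants and matches the normal tail", {
  expect_warning(rep0 <- univariate_outliers(rep(2, 10)), "zero")
  expect_equal(rep0$n_flagged, 0L)
  # with known moments the mean flag count matches 55 x 2 Phi(-3.29)
  set.seed(13)
  counts <- replicate(1000, {
    x <- stats::rnorm(55)
    univariate_outliers(x, center = 0, scale = 1)$n_flagged
  })
  expect_lt(abs(mean(counts) - 55 * 2 * stats::pnorm(-3.29)), 0.03)
})

test_that("Mahalanobis rule: planted outlier, null rate, univariate identity", {
  set.seed(14)
  X <- matrix(stats::rnorm(200 * 3), 200, 3)
  X[7, ] <- 10
  rep <- mahalanobis_outliers(X)
  expect_true(7 %in% rep$flagged)

  big <- matrix(stats::rnorm(50000 * 3), ncol = 3)
  rate <- mahalanobis_outliers(big)$n_flagged / 50000
  expect_gt(rate, 0.0004)
  expect_lt(rate, 0.002)

  # p = 1: D^2 equals z^2, so the chi-square(1) cut at p = 0.001 flags the
  # same observations as the 3.2905-SD univariate rule
  x <- c(stats::rnorm(100), 6)
  m1 <- mahalanobis_outliers(cbind(x))
  u1 <- univariate_outliers(x, threshold_sd = sqrt(stats::qchisq(0.999, 1)))
  expect_equal(m1$flagged, u1$flagged)
  # note the sample-variance denominators differ (n-1 vs mahalanobis' n-1) --
  # both use stats::cov/sd, so D^2 = ((x-mean)/sd)^2 exactly
  expect_equal(unname(m1$d2), unname(u1$z^2), tolerance = 1e-12)

  sing <- cbind(x, 2 * x)
  expect_error(mahalanobis_outliers(sing), "singular")
})

test_that("log lesion transform normalizes the generator's volume distribution", {
  expect_equal(log_lesion_transform(1.0)$log_volumes, 0)
  expect_error(log_lesion_transform(c(1, -2)), "> 0")
  co <- generate_cohort(cohort_spec(n_subjects = 10000, seed = 15),
                        tacs = FALSE)$cohort
  tr <- log_lesion_transform(co$lesion_ml)
  expect_gt(tr$before$skewness, 1)
  expect_lt(abs(tr$after$skewness), 0.5)
})

test_that("describe_moments follows the excess-kurtosis convention", {
  expect_equal(describe_moments(c(1, 2, 3, 4))$mean, 2.5)
  set.seed(16)
  d <- describe_moments(stats::rnorm(50000))
  expect_lt(abs(d$skewness), 0.05)
  expect_lt(abs(d$kurtosis_excess), 0.1)
  # log-normal before transform is positively skewed
  expect_gt(describe_moments(exp(stats::rnorm(5000)))$skewness, 1)
})

test_that("partial correlation matches the single-covariate closed form", {
  set.seed(17)
  for (i in 1:10) {
    n <- 60
    z <- stats::rnorm(n)
    x <- 0.5 * z + stats::rnorm(n)
    y <- -0.3 * z + 0.4 * x + stats::rnorm(n)
    r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
    closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
    res <- partial_correlation(x, y, z)
    expect_equal(res$r, closed, tolerance = 1e-10)
    expect_equal(res$df, n - 3)
  }
})

test_that("partial correlation limit cases behave", {
  set.seed(18)
  n <- 20000
  x <- stats::rnorm(n); y <- 0.4 * x + stats::rnorm(n); z <- stats::rnorm(n)
  expect_equal(partial_correlation(x, y, z)$r, partial_correlation(x, y)$r,
               tolerance = 0.02)
  expect_equal(partial_correlation(x, x)$r, 1)
  expect_error(partial_correlation(x[1:8], y[1:8], cbind(z[1:8], z[1:8])),
               "collinear")
})

test_that("hierarchical regression recovers the generating coefficient", {
  set.seed(19)
  n <- 10000
  age <- stats::rnorm(n)
  x1 <- stats::rnorm(n)
  y <- 0.45 * x1 + stats::rnorm(n, 0, sqrt(1 - 0.45^2))
  d <- data.frame(y = y, age = age, x1 = x1)
  hr <- hierarchical_regression(d, "y", list("age", "x1"))
  b <- hr$models[[2]]$table
  expect_equal(b$beta[b$variable == "x1"], 0.45, tolerance = 0.03)
  # single-predictor standardized beta is the Pearson r, exactly
  hr1 <- hierarchical_regression(d, "y", list("x1"))
  expect_equal(hr1$models[[1]]$table$beta, stats::cor(y, x1), tolerance = 1e-12)
})

test_that("R2-change F test agrees with the nested-model anova oracle", {
  set.seed(20)
  n <- 80
  d <- data.frame(
    y = stats::rnorm(n), a = stats::rnorm(n), b = stats::rnorm(n),
    c = stats::rnorm(n)
  )
  hr <- hierarchical_regression(d, "y", list("a", c("b", "c")))
  zd <- as.data.frame(lapply(d, zscore))
  f_red <- stats::lm(y ~ a, data = zd)
  f_full <- stats::lm(y ~ a + b + c, data = zd)
  an <- stats::anova(f_red, f_full)
  m2 <- hr$models[[2]]
  expect_equal(m2$f_change, an$F[2], tolerance = 1e-10)
  expect_equal(m2$p_change, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(m2$delta_r2,
               summary(f_full)$r.squared - summary(f_red)$r.squared,
               tolerance = 1e-10)
  # adjusted R2 never exceeds R2; partial r signs track beta signs
  for (m in hr$models) {
    expect_lte(m$adj_r_squared, m$r_squared)
    expect_true(all(sign(m$table$partial_r) == sign(m$table$beta)))
  }
  d$dup <- d$a
  expect_error(hierarchical_regression(d, "y", list(c("a", "dup"))),
               "collinear")
})

test_that("group comparisons cover t, ANCOVA and chi-square", {
  g <- rep(c("m", "f"), each = 10)
  v <- rep(1:10, 2)
  tt <- group_compare(v, g)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$df, 18)

  # simulated male/female difference of 0.62 z at n = 27/28: mean t near 2.4
  set.seed(21)
  ts <- replicate(500, {
    # factor levels order men first ("m" < "w") so the difference is m - w
    group_compare(c(stats::rnorm(27, 0.62), stats::rnorm(28)),
                  rep(c("m", "w"), c(27, 28)))$statistic
  })
  expect_equal(mean(ts), 2.4, tolerance = 0.15)

  set.seed(22)
  cov <- stats::rnorm(20)
  an <- group_compare(v + cov, g, covariates = cov)
  expect_equal(an$method, "ANCOVA")
  expect_true(is.finite(an$statistic))

  tab_vals <- rep(c("yes", "no"), c(20, 20))
  tab_grp <- rep(c("a", "b"), 20)
  ch <- group_compare(tab_vals, tab_grp)
  expect_equal(ch$method, "chi-square")
  expect_equal(ch$statistic, 0)
  expect_error(group_compare(v, rep("m", 20)), "two")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 10), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.3), 1), c(0.2, 0.3))
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("power analysis: closed form, limits, and simulation oracle", {
  expect_equal(power_min_n(0.15, 0.05, 0.80, 1, 1), 55)
  # 1 to 3 tested predictors: N grows with df1
  expect_gt(power_min_n(0.15, 0.05, 0.80, 3, 1), power_min_n(0.15, 0.05, 0.80, 1, 1))
  # enormous effect: N collapses to the smallest model that leaves df2 >= 1
  expect_lte(power_min_n(1e6, 0.05, 0.80, 1, 1), 5)
  expect_error(power_min_n(-0.1), "> 0")
  # the alternative noncentrality convention is exposed and close by
  expect_lt(abs(power_min_n(0.15, ncp_convention = "df") - 55), 3)

  # simulation oracle with a fixed design at exact noncentrality f2 * N:
  # empirical rejection of the R2-change test matches power_at_n within 0.02
  N <- 55
  set.seed(23)
  x1 <- zscore(stats::rnorm(N))
  x2r <- stats::resid(stats::lm(stats::rnorm(N) ~ x1))
  x2 <- x2r / sqrt(sum(x2r^2) / N) # x2' M x2 = N exactly
  b <- sqrt(0.15)
  rej <- replicate(5000, {
    y <- b * x2 + stats::rnorm(N)
    d <- data.frame(y = y, x1 = x1, x2 = x2)
    hr <- hierarchical_regression(d, "y", list("x1", "x2"))
    hr$models[[2]]$p_change < 0.05
  })
  expect_equal(mean(rej), power_at_n(N), tolerance = 0.02)
})
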