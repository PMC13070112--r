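test_that("MRTM recovers coefficients exactly on operational-equation data", {
  # build a target satisfying C_T = b1 int C_R + b2 int C_T + b3 C_R by
  # forward recursion under the same frame-average integral convention the
  # fitter uses; recovery must then be exact
  b <- c(-0.3, 0.1, -0.5)
  ref <- ref_pe2i()
  s <- ref$schedule
  d <- frame_durations_min(s)
  A <- running_integral(ref)
  ct <- numeric(s$n_frames)
  int_ct <- 0
  for (j in seq_len(s$n_frames)) {
    # int to midpoint j = int_ct + ct[j] * d[j] / 2
    rhs <- b[1] * A[j] + b[2] * int_ct + b[3] * ref$activity[j]
    ct[j] <- rhs / (1 - b[2] * d[j] / 2)
    int_ct <- int_ct + ct[j] * d[j]
  }
  fit <- fit_mrtm(tac(s, ct), ref)
  expect_equal(unname(fit$coefficients), b, tolerance = 1e-10)
  expect_equal(fit$estimate, -b[1] / b[2] - 1, tolerance = 1e-10) # = 2.0
  expect_equal(fit$estimate, 2.0, tolerance = 1e-10)
})

test_that("noise-free SRTM round trips recover BP_ND within 1% across a grid", {
  ref <- ref_pe2i()
  for (bp in c(0.5, 1, 2, 2.24, 3, 3.31, 4)) {
    tg <- simulate_reversible_tac(ref, R1 = 0.9, k2 = 0.15, bp_nd = bp)
    fit <- fit_mrtm(tg, ref)
    expect_lt(abs(fit$estimate - bp) / bp, 0.01)
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("MRTM estimates are monotone in the simulated BP_ND", {
  ref <- ref_pe2i()
  grid <- seq(0.25, 4.5, by = 0.25)
  est <- vapply(grid, function(bp) {
    fit_mrtm(simulate_reversible_tac(ref, 0.9, 0.15, bp), ref)$estimate
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("MRTM and Patlak are invariant under joint rescaling of both TACs", {
  ref <- ref_pe2i()
  tg <- simulate_reversible_tac(ref, 0.9, 0.15, 2.5)
  f1 <- fit_mrtm(tg, ref)
  f2 <- fit_mrtm(
    tac(tg$schedule, tg$activity * 5),
    tac(ref$schedule, ref$activity * 5)
  )
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)

  sim <- simulate_irreversible_tac(ref_ded(), 0.07, 1.0)
  p1 <- fit_reference_patlak(sim$target, sim$cerebellum)
  p2 <- fit_reference_patlak(
    tac(sim$target$schedule, sim$target$activity * 5),
    tac(sim$cerebellum$schedule, sim$cerebellum$activity * 5)
  )
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-12)
})

test_that("Patlak is exact on data built from the operational equation", {
  # target assembled framewise from the corrected reference and the same
  # integral convention: slope and intercept recover to machine precision
  cer <- ref_ded()
  t_min <- frame_midpoints(cer$schedule)
  lam <- 0.04
  ref_corr <- cer$activity * exp(-lam * t_min)
  ref_tac <- tac(cer$schedule, ref_corr)
  ki <- 0.07; v0 <- 1.0
  target <- tac(cer$schedule, ki * running_integral(ref_tac) + v0 * ref_corr)
  fit <- fit_reference_patlak(target, cer, patlak_config(lambda_bar = lam))
  expect_equal(fit$estimate, ki, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["intercept"]), v0, tolerance = 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-12)
})

test_that("noise-free irreversible round trips recover Ki within 1%", {
  ref <- ref_ded()
  for (ki in c(0.02, 0.04, 0.07)) {
    sim <- simulate_irreversible_tac(ref, ki, 1.5)
    fit <- fit_reference_patlak(sim$target, sim$cerebellum)
    expect_lt(abs(fit$estimate - ki) / ki, 0.01)
  }
})

test_that("singular and invalid fits raise errors rather than answers", {
  ref <- ref_pe2i()
  # target proportional to reference -> integral columns collinear
  prop <- tac(ref$schedule, ref$activity * 2)
  expect_error(fit_mrtm(prop, ref), "singular|collinear")
  short <- frame_schedule(c(60, 60, 60))
  expect_error(
    fit_mrtm(tac(short, 1:3), tac(short, c(2, 4, 6))),
    "at least 4 frames"
  )
  expect_error(
    fit_reference_patlak(ref, ref, patlak_config(fit_frames = 4:26)),
    "frame 26 but schedule has 18"
  )
  expect_error(patlak_config(fit_frames = 4:5), "at least 3")
  neg <- tac(ded_frame_schedule(), rep(-1, 26))
  expect_error(fit_reference_patlak(neg, neg), "nonpositive")
})

test_that("QR fits agree with brute-force normal equations", {
  set.seed(4)
  ref <- ref_pe2i()
  for (i in 1:5) {
    tg <- add_frame_noise(simulate_reversible_tac(ref, 0.9, 0.15, 2), 0.3)
    fit <- fit_mrtm(tg, ref)
    X <- cbind(running_integral(ref), running_integral(tg), ref$activity)
    oracle <- ols_normal_equations(X, tg$activity)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-8)
  }
})

test_that("radioactive decay fractions are exact", {
  expect_equal(decay_remaining_fraction(20.36, 0), 1.0)
  expect_equal(decay_remaining_fraction(20.36, 20.36), 0.5)
  # 11C after 3.5 h: about 8e-4, under the 0.2% bound
  expect_equal(decay_remaining_fraction(20.36, 210), 2^(-210 / 20.36))
  expect_lt(decay_remaining_fraction(20.36, 210), 0.002)
  expect_error(decay_remaining_fraction(0, 10), "> 0")
  expect_error(decay_remaining_fraction(20, -1), ">= 0")
})
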