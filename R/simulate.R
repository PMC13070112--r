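# Forward TAC simulation.
#
# The reference-curve family is a two-exponential difference
#   C_R(t) = A (e^{-l1 t} - e^{-l2 t}),  l2 > l1 > 0,
# which is smooth, positive, peaks inside the scan window, and -- crucially --
# closed under every operation the forward models need: convolution with an
# exponential (reversible model), running integration (irreversible model),
# and multiplication by e^{ct} (the emitted cerebellum curve). All simulated
# activities are therefore sums of exponentials, and per-frame averages are
# computed exactly by analytic integration rather than on a discrete grid.

# sum-of-exponentials representation: sum_i coef[i] * exp(-rate[i] * t);
# rate 0 encodes a constant term, negative rates encode growing exponentials.
expsum <- function(coef, rate) list(coef = as.numeric(coef), rate = as.numeric(rate))

expsum_eval <- function(es, t) {
  drop(exp(-outer(t, es$rate)) %*% es$coef)
}

# running integral from 0: int_0^t c e^{-a u} du = c (1 - e^{-a t}) / a
expsum_integral <- function(es) {
  coef <- es$coef
  rate <- es$rate
  out_coef <- numeric(0)
  out_rate <- numeric(0)
  for (i in seq_along(coef)) {
    if (abs(rate[i]) < 1e-12) { # constant -> linear term not representable;
      stop("expsum_integral: constant terms unsupported") # never needed here
    }
    out_coef <- c(out_coef, coef[i] / rate[i], -coef[i] / rate[i])
    out_rate <- c(out_rate, 0, rate[i])
  }
  expsum(out_coef, out_rate)
}

# exact mean over [s, e]: (1/(e-s)) int_s^e coef e^{-a t} dt
expsum_frame_average <- function(es, schedule) {
  s <- schedule$start_s / 60
  e <- (schedule$start_s + schedule$duration_s) / 60
  dur <- e - s
  out <- numeric(schedule$n_frames)
  for (i in seq_along(es$coef)) {
    a <- es$rate[i]
    if (abs(a) < 1e-12) {
      out <- out + es$coef[i]
    } else {
      out <- out + es$coef[i] * (exp(-a * s) - exp(-a * e)) / (a * dur)
    }
  }
  out
}

# convolution with e^{-k t}:
# conv(e^{-a t}, e^{-k t}) = (e^{-a t} - e^{-k t}) / (k - a).
# When k coincides with a curve rate the limit is t e^{-a t}; rather than
# widen the representation with polynomial terms, nudge k by 1e-7/min,
# which perturbs the curve by under 1e-5 of its value over a 55-min scan.
expsum_conv_exp <- function(es, k) {
  out_coef <- numeric(0)
  out_rate <- numeric(0)
  if (any(abs(k - es$rate) < 1e-7)) k <- k + 2e-7
  for (i in seq_along(es$coef)) {
    a <- es$rate[i]
    out_coef <- c(out_coef, es$coef[i] / (k - a), -es$coef[i] / (k - a))
    out_rate <- c(out_rate, a, k)
  }
  expsum(out_coef, out_rate)
}

# multiply by e^{-c t}: shifts every rate by +c
expsum_shift <- function(es, c) expsum(es$coef, es$rate + c)

tac_with_expsum <- function(schedule, es, region) {
  out <- tac(schedule, expsum_frame_average(es, schedule), region)
  attr(out, "expsum") <- es
  out
}

get_expsum <- function(x, what) {
  es <- attr(x, "expsum")
  if (is.null(es)) {
    stop(sprintf(
      "%s must carry the analytic curve model produced by make_reference_tac()",
      what
    ))
  }
  es
}

# run expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a reference-region time-activity curve
#'
#' Generates a cerebellum-like reference curve of the form
#' `C_R(t) = A (exp(-lambda1 t) - exp(-lambda2 t))` (rates in 1/min,
#' `lambda2 > lambda1 > 0`), evaluated as exact per-frame averages on the
#' given schedule. The analytic curve model is attached to the result so
#' that forward simulators can use it without numerical convolution.
#'
#' @param schedule a [frame_schedule()].
#' @param amplitude peak-scale coefficient A (kBq/ml).
#' @param lambda1 slow rate constant (1/min), the terminal washout.
#' @param lambda2 fast rate constant (1/min), the delivery phase;
#'   must exceed `lambda1`.
#' @param region region label.
#' @return A [tac()] with the analytic model attached.
#' @export
make_reference_tac <- function(schedule, amplitude = 100, lambda1 = 0.05,
                               lambda2 = 1.0, region = "cerebellum") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (!is.finite(lambda1) || !is.finite(lambda2) || lambda1 <= 0 || lambda2 <= 0) {
    stop("rate constants must be positive")
  }
  if (abs(lambda2 - lambda1) < 1e-8) {
    stop("degenerate reference shape: rate constants must be distinct")
  }
  if (lambda2 < lambda1) stop("lambda2 must exceed lambda1")
  es <- expsum(c(amplitude, -amplitude), c(lambda1, lambda2))
  tac_with_expsum(schedule, es, region)
}

#' Simulate a reversible-tracer target TAC (SRTM forward model)
#'
#' Solves the simplified reference tissue model forward:
#' `C_T(t) = R1 C_R(t) + (k2 - R1 k2a) [C_R (x) exp(-k2a t)](t)` with
#' `k2a = k2 / (1 + BP_ND)`. With the analytic two-exponential reference the
#' convolution is exact, and the returned activities are exact frame
#' averages.
#'
#' @param ref reference [tac()] from [make_reference_tac()].
#' @param R1 delivery ratio K1/K1' (unitless, > 0).
#' @param k2 reference-region efflux constant (1/min, > 0).
#' @param bp_nd true non-displaceable binding potential (>= 0).
#' @param region region label.
#' @return A [tac()] on the reference's schedule.
#' @export
simulate_reversible_tac <- function(ref, R1, k2, bp_nd, region = "target") {
  stopifnot(inherits(ref, "tac"))
  if (!is.finite(bp_nd) || bp_nd < 0) stop("bp_nd must be >= 0")
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be > 0")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0")
  es_ref <- get_expsum(ref, "ref")
  k2a <- k2 / (1 + bp_nd)
  conv <- expsum_conv_exp(es_ref, k2a)
  es_t <- expsum(
    c(R1 * es_ref$coef, (k2 - R1 * k2a) * conv$coef),
    c(es_ref$rate, conv$rate)
  )
  tac_with_expsum(ref$schedule, es_t, region)
}

#' Simulate an irreversible-tracer target TAC and its cerebellum curve
#'
#' Builds the target as `C_T(t) = Ki int_0^t C_ref(u) du + V0 C_ref(t)`,
#' i.e. exactly the reference-Patlak operational model with slope `Ki` and
#' intercept `V0`. The emitted cerebellum curve is
#' `C_cer(t) = C_ref(t) exp(+lambda_bar t)`, so that the estimator's
#' reference correction `C_cer(t) exp(-lambda_bar t)` inverts it exactly.
#'
#' @param ref_corrected the (already-corrected) reference [tac()] from
#'   [make_reference_tac()]; must be strictly positive after the first frame.
#' @param ki true uptake rate constant (1/min, >= 0).
#' @param v0 true distribution-volume intercept (unitless).
#' @param lambda_bar correction constant used to emit the cerebellum curve
#'   (1/min; default 0.04, the published value).
#' @return A list with elements `target` and `cerebellum`, both [tac()]s.
#' @export
simulate_irreversible_tac <- function(ref_corrected, ki, v0,
                                      lambda_bar = 0.04, region = "target") {
  stopifnot(inherits(ref_corrected, "tac"))
  if (!is.finite(ki) || ki < 0) stop("ki must be >= 0")
  if (any(ref_corrected$activity[-1] <= 0)) {
    stop("ref_corrected must be strictly positive after the first frame")
  }
  es_ref <- get_expsum(ref_corrected, "ref_corrected")
  es_int <- expsum_integral(es_ref)
  es_t <- expsum(
    c(ki * es_int$coef, v0 * es_ref$coef),
    c(es_int$rate, es_ref$rate)
  )
  es_cer <- expsum_shift(es_ref, -lambda_bar)
  list(
    target = tac_with_expsum(ref_corrected$schedule, es_t, region),
    cerebellum = tac_with_expsum(ref_corrected$schedule, es_cer, "cerebellum")
  )
}

#' Add frame-weighted Gaussian noise to a TAC
#'
#' Adds zero-mean Gaussian noise with per-frame standard deviation
#' `noise_scale * sqrt(max(C_j, eps) / dt_j)` (dt in minutes), the standard
#' count-statistics approximation for decay-corrected framewise PET data:
#' variance grows with activity and shrinks with frame duration.
#'
#' @param x a [tac()].
#' @param noise_scale nonnegative noise coefficient; 0 returns `x` unchanged.
#' @param seed optional integer; when given, noise is drawn from a private
#'   RNG stream and the global RNG state is left untouched.
#' @param eps activity floor used inside the square root.
#' @return A [tac()] with noisy activities (analytic curve model dropped).
#' @export
add_frame_noise <- function(x, noise_scale, seed = NULL, eps = 1e-3) {
  stopifnot(inherits(x, "tac"))
  if (!is.finite(noise_scale) || noise_scale < 0) stop("noise_scale must be >= 0")
  if (noise_scale == 0) return(x)
  sd_j <- noise_scale * sqrt(pmax(x$activity, eps) / frame_durations_min(x$schedule))
  noise <- with_seed(seed, stats::rnorm(length(sd_j), 0, sd_j))
  tac(x$schedule, x$activity + noise, x$region)
}
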