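#' @name kinetics
#' @title Reference-tissue kinetic estimators
#' @description
#' Two estimators cover the two tracers: [fit_mrtm()] for the reversible DAT
#' ligand (multilinear reference tissue model, all frames) and
#' [fit_reference_patlak()] for the irreversible MAO-B ligand (reference
#' Patlak with an exponential reference-kinetics correction, late frames
#' only). Both treat input TACs as decay-corrected; the Patlak
#' `exp(-lambda_bar t)` term is a reference-kinetics adjustment, not isotope
#' decay (see [decay_remaining_fraction()] for the latter).
NULL

#' Reference-Patlak configuration
#'
#' @param lambda_bar reference-kinetics correction constant (1/min); the
#'   reference used in the Patlak plot is `C_cer(t) * exp(-lambda_bar * t)`.
#'   Default 0.04, the published value for the deuterated-deprenyl method.
#' @param fit_frames inclusive 1-based frame-index window used for the
#'   linear fit; default 4:26, the steady-state phase of the 26-frame
#'   schedule.
#' @return An object of class `patlak_config`.
#' @export
patlak_config <- function(lambda_bar = 0.04, fit_frames = 4:26) {
  if (!is.finite(lambda_bar) || lambda_bar < 0) stop("lambda_bar must be >= 0")
  fit_frames <- as.integer(fit_frames)
  if (length(fit_frames) < 3) stop("fit window must contain at least 3 frames")
  if (any(fit_frames < 1) || any(diff(fit_frames) != 1L)) {
    stop("fit_frames must be a contiguous 1-based index window")
  }
  structure(list(lambda_bar = lambda_bar, fit_frames = fit_frames),
            class = "patlak_config")
}

new_kinetic_fit <- function(model, coefficients, estimate, rss, r_squared,
                            n_frames) {
  structure(
    list(
      model = model, coefficients = coefficients, estimate = estimate,
      rss = rss, r_squared = r_squared, n_frames = n_frames
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  lab <- if (x$model == "MRTM") "BP_ND" else "Ki_ref"
  cat(sprintf(
    "<kinetic_fit> %s: %s = %.4g (R^2 = %.5f, %d frames)\n",
    x$model, lab, x$estimate, x$r_squared, x$n_frames
  ))
  invisible(x)
}

# OLS via QR with an explicit rank check; singular designs must raise,
# never silently pseudo-invert.
ols_strict <- function(X, y, what) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop(sprintf("singular design in %s: predictors are collinear", what))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(beta = beta, rss = rss, r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Fit the multilinear reference tissue model (MRTM)
#'
#' Estimates BP_ND of a reversible tracer by ordinary least squares on the
#' operational equation over all frames:
#' `C_T(T) = b1 int_0^T C_R + b2 int_0^T C_T + b3 C_R(T)`,
#' with `BP_ND = -b1/b2 - 1`. For data following the simplified reference
#' tissue model, `b1 = k2`, `b2 = -k2a`, `b3 = R1`.
#'
#' @param target target-region [tac()].
#' @param reference reference-region [tac()] on the same schedule.
#' @return A `kinetic_fit` with model `"MRTM"`, coefficients `b1..b3`,
#'   `estimate` = BP_ND, residual sum of squares and operational-fit R^2.
#' @export
fit_mrtm <- function(target, reference) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (!identical(target$schedule$duration_s, reference$schedule$duration_s)) {
    stop("target and reference must share one frame schedule")
  }
  n <- target$schedule$n_frames
  if (n < 4) stop("MRTM needs at least 4 frames")
  X <- cbind(
    int_ref = running_integral(reference),
    int_tgt = running_integral(target),
    ref = reference$activity
  )
  fit <- ols_strict(X, target$activity, "fit_mrtm")
  b <- fit$beta
  if (abs(b[2]) < .Machine$double.eps) stop("MRTM: b2 is zero, BP_ND undefined")
  new_kinetic_fit(
    "MRTM", stats::setNames(b, c("b1", "b2", "b3")),
    estimate = unname(-b[1] / b[2] - 1),
    rss = fit$rss, r_squared = fit$r_squared, n_frames = n
  )
}

#' Fit the reference-Patlak model with exponential reference correction
#'
#' Computes the corrected reference `C_ref(t) = C_cer(t) exp(-lambda_bar t)`
#' and regresses `y = C_T(t)/C_ref(t)` on
#' `x = int_0^t C_ref(u) du / C_ref(t)` over the configured frame window.
#' The slope is the uptake rate constant Ki_ref (1/min); the intercept is an
#' effective distribution volume. Both axes are normalized by the corrected
#' reference, so the estimate is invariant under joint rescaling of the two
#' TACs.
#'
#' @param target target-region [tac()].
#' @param cerebellum uncorrected cerebellum [tac()] on the same schedule.
#' @param config a [patlak_config()].
#' @return A `kinetic_fit` with model `"refPatlak"`, coefficients
#'   `(intercept, slope)`, `estimate` = Ki_ref, residual sum of squares and
#'   fit R^2 over the window.
#' @export
fit_reference_patlak <- function(target, cerebellum, config = patlak_config()) {
  stopifnot(inherits(target, "tac"), inherits(cerebellum, "tac"),
            inherits(config, "patlak_config"))
  if (!identical(target$schedule$duration_s, cerebellum$schedule$duration_s)) {
    stop("target and cerebellum must share one frame schedule")
  }
  n <- target$schedule$n_frames
  w <- config$fit_frames
  if (max(w) > n) stop(sprintf("fit window runs to frame %d but schedule has %d frames",
                               max(w), n))
  t_min <- frame_midpoints(target$schedule)
  ref <- cerebellum$activity * exp(-config$lambda_bar * t_min)
  if (any(ref[w] <= 0)) stop("corrected reference is nonpositive inside the fit window")
  ref_tac <- tac(cerebellum$schedule, ref, "reference_corrected")
  x <- running_integral(ref_tac) / ref
  y <- target$activity / ref
  X <- cbind(intercept = 1, x = x[w])
  fit <- ols_strict(X, y[w], "fit_reference_patlak")
  new_kinetic_fit(
    "refPatlak",
    stats::setNames(fit$beta, c("intercept", "slope")),
    estimate = unname(fit$beta[2]),
    rss = fit$rss, r_squared = fit$r_squared, n_frames = length(w)
  )
}

#' Fraction of activity remaining after radioactive decay
#'
#' @param half_life_min isotope half-life in minutes (> 0); 20.36 for 11C.
#' @param elapsed_min elapsed time in minutes (>= 0).
#' @return `2^(-elapsed/half_life)`, the remaining fraction.
#' @examples
#' decay_remaining_fraction(20.36, 210) # < 0.002 after 3.5 h
#' @export
decay_remaining_fraction <- function(half_life_min, elapsed_min) {
  if (any(!is.finite(half_life_min)) || any(half_life_min <= 0)) {
    stop("half_life_min must be > 0")
  }
  if (any(!is.finite(elapsed_min)) || any(elapsed_min < 0)) {
    stop("elapsed_min must be >= 0")
  }
  2^(-elapsed_min / half_life_min)
}
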