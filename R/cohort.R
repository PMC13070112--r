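# Synthetic cohort generation.
#
# Constructs are drawn from a multivariate normal over seven latents
# {age, sex, bmi, dat, maob, lesion, cognition}. Calibration targets are the
# *observed* correlations a study of this design reports: regional scores and
# test scores carry uniqueness/noise, so every printed correlation involving
# a composite (DAT z-composite, MAO-B factor, general cognition, binary sex)
# is attenuated relative to the corresponding latent correlation. The
# generator therefore divides each target by the closed-form attenuation
# factors of the composites involved before drawing latents, so that the
# measured pipeline output is centered on the printed values.

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping at `eigen_floor` followed by re-standardization to a
#' unit diagonal. Used to repair mildly indefinite target matrices assembled
#' from separately reported correlations.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eigen_floor smallest eigenvalue allowed after projection.
#' @param max_shift largest admissible change to any entry; beyond this the
#'   target matrix is rejected as inconsistent rather than silently warped.
#' @return A positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(R, eigen_floor = 1e-8, max_shift = 0.1) {
  if (max(abs(R - t(R))) > 1e-10) stop("matrix must be symmetric")
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) >= eigen_floor) return(R)
  lam <- pmax(eig$values, eigen_floor)
  R2 <- eig$vectors %*% diag(lam) %*% t(eig$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  if (max(abs(R2 - R)) > max_shift) {
    stop("correlation matrix is not PSD within projection tolerance")
  }
  dimnames(R2) <- dimnames(R)
  R2
}

# zero-order correlation implied by a partial correlation given one shared
# covariate z: r_xy = r_xy.z * sqrt((1-r_xz^2)(1-r_yz^2)) + r_xz r_yz
zero_order_from_partial <- function(r_partial, r_xz, r_yz) {
  r_partial * sqrt((1 - r_xz^2) * (1 - r_yz^2)) + r_xz * r_yz
}

#' Default observed-scale construct correlation targets
#'
#' The 7 x 7 target correlation matrix over
#' `{age, sex, bmi, dat, maob, lesion, cognition}` on the scale of the
#' measured analysis variables (DAT z-composite, MAO-B factor score,
#' log-lesion volume, general-cognition composite, male = 1). Entries come
#' from the reported cohort: zero-order correlations with age, sex effects
#' converted from t statistics, BMI associations, and the age-adjusted
#' partial correlations among the brain/cognition constructs converted to
#' zero-order values in closed form.
#'
#' @return Named 7 x 7 correlation matrix.
#' @export
default_construct_correlations <- function() {
  v <- c("age", "sex", "bmi", "dat", "maob", "lesion", "cognition")
  R <- diag(7)
  dimnames(R) <- list(v, v)
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  # zero-order with age
  set("age", "dat", -0.20)
  set("age", "maob", 0.36)
  set("age", "lesion", 0.42)
  set("age", "cognition", -0.50)
  # sex (male = 1): point-biserial r = t / sqrt(t^2 + df)
  set("sex", "dat", 2.4 / sqrt(2.4^2 + 49))
  set("sex", "maob", 1.3 / sqrt(1.3^2 + 53))
  set("sex", "lesion", 0.7 / sqrt(0.7^2 + 52))
  set("sex", "cognition", 0.5 / sqrt(0.5^2 + 42))
  # BMI associations with ligand uptake and cognition
  set("bmi", "dat", -0.53)
  set("bmi", "maob", -0.43)
  set("bmi", "cognition", -0.05)
  # age-adjusted partials among brain/cognition constructs -> zero-order
  set("dat", "maob", zero_order_from_partial(0.53, R["age", "dat"], R["age", "maob"]))
  set("dat", "lesion", zero_order_from_partial(-0.39, R["age", "dat"], R["age", "lesion"]))
  set("maob", "lesion", zero_order_from_partial(-0.33, R["age", "maob"], R["age", "lesion"]))
  set("dat", "cognition", zero_order_from_partial(0.42, R["age", "dat"], R["age", "cognition"]))
  set("maob", "cognition", zero_order_from_partial(-0.05, R["age", "maob"], R["age", "cognition"]))
  set("lesion", "cognition", zero_order_from_partial(-0.01, R["age", "lesion"], R["age", "cognition"]))
  R
}

# attenuation of a k-region equicorrelated composite relative to its latent:
# corr(mean of k unit-variance region scores each loading sqrt(rho), latent)
equicorr_attenuation <- function(rho, k) sqrt(k * rho / (1 + (k - 1) * rho))

# attenuation of the general-cognition composite: domains load sqrt(gamma2)
# on the general latent; tests load sqrt(reliability) on their domain;
# domain scores are means of test z-scores, general is the mean of domains.
cognition_attenuation <- function(gamma2, reliabilities_by_domain) {
  gam <- sqrt(gamma2)
  s <- vapply(reliabilities_by_domain, function(r) mean(sqrt(r)), numeric(1))
  v <- vapply(reliabilities_by_domain, function(r) {
    sq <- sqrt(r)
    (length(r) + 2 * (sum(sq)^2 - sum(r)) / 2) / length(r)^2
  }, numeric(1))
  k <- length(s)
  cov_gG <- gam * mean(s)
  var_g <- (sum(v) + gamma2 * (sum(s)^2 - sum(s^2))) / k^2
  cov_gG / sqrt(var_g)
}

#' Synthetic cohort specification
#'
#' Collects every tunable of the generator with defaults calibrated to the
#' printed cohort: demographic moments, Table-2 regional kinetic means/SDs,
#' inter-regional correlations, the construct correlation targets, the
#' log-normal lesion model (matched to mean 2.0 ml, SD 2.9 ml), the nine-test
#' battery with its reliabilities, and the TAC noise level.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#' @param correlations observed-scale construct correlation targets
#'   (default [default_construct_correlations()]).
#' @param noise_scale TAC noise coefficient for [add_frame_noise()]; the
#'   default 0.15 gives 1-3% noise on late frames of ROI-averaged curves.
#' @param bp_means,bp_sds named (caudate, putamen) means/SDs of true BP_ND.
#' @param ki_means,ki_sds named regional means/SDs of true Ki_ref (1/min).
#' @param dat_region_cor caudate-putamen correlation of true BP_ND.
#' @param ki_region_cor common inter-regional correlation of true Ki_ref.
#' @param gamma2 squared loading of each cognitive domain on the general
#'   factor.
#' @param lesion_mean_ml,lesion_sd_ml moments of the log-normal lesion
#'   volume distribution.
#' @param inject_extreme_lesion_ml optional volume (ml) planted on one
#'   subject to exercise the univariate outlier rule (e.g. 14.7).
#' @param emulate_missingness if TRUE, reproduce the study's missing-data
#'   pattern: the first 10 subjects have episodic tests only, one further
#'   subject working-memory tests only, and 4 subjects miss the DAT scan.
#' @param age_mean,age_sd,bmi_mean,bmi_sd demographic moments.
#' @param hypertension_prev prevalence of the hypertension flag.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 55, seed = 1,
                        correlations = default_construct_correlations(),
                        noise_scale = 0.15,
                        bp_means = c(caudate = 2.24, putamen = 3.31),
                        bp_sds = c(caudate = 0.52, putamen = 0.59),
                        ki_means = c(caudate = 0.06, putamen = 0.07,
                                     thalamus = 0.06, hippocampus = 0.05,
                                     cortex = 0.04),
                        ki_sds = c(caudate = 0.010, putamen = 0.004,
                                   thalamus = 0.004, hippocampus = 0.004,
                                   cortex = 0.004),
                        dat_region_cor = 0.78,
                        ki_region_cor = 0.67,
                        gamma2 = 0.6,
                        lesion_mean_ml = 2.0, lesion_sd_ml = 2.9,
                        inject_extreme_lesion_ml = NULL,
                        emulate_missingness = FALSE,
                        age_mean = 67.4, age_sd = 5.1,
                        bmi_mean = 27.4, bmi_sd = 5.5,
                        hypertension_prev = 0.55) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  stopifnot(
    identical(dim(correlations), c(7L, 7L)),
    all(diag(correlations) == 1),
    max(abs(correlations - t(correlations))) < 1e-10
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      correlations = correlations, noise_scale = noise_scale,
      bp_means = bp_means, bp_sds = bp_sds,
      ki_means = ki_means, ki_sds = ki_sds,
      dat_region_cor = dat_region_cor, ki_region_cor = ki_region_cor,
      gamma2 = gamma2,
      lesion_mean_ml = lesion_mean_ml, lesion_sd_ml = lesion_sd_ml,
      inject_extreme_lesion_ml = inject_extreme_lesion_ml,
      emulate_missingness = isTRUE(emulate_missingness),
      age_mean = age_mean, age_sd = age_sd,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      hypertension_prev = hypertension_prev
    ),
    class = "cohort_spec"
  )
}

# latent-scale correlation matrix: observed targets disattenuated by the
# composite reliabilities, then PSD-projected
latent_correlations <- function(spec) {
  specs <- cognitive_test_specs()
  rel <- split(specs$reliability, specs$domain)[c("episodic", "working", "speed")]
  lambda <- c(
    age = 1,
    sex = sqrt(2 / pi), # median split of a standard normal latent
    bmi = 1,
    dat = equicorr_attenuation(spec$dat_region_cor, 2),
    maob = equicorr_attenuation(spec$ki_region_cor, 3),
    lesion = 1,
    cognition = cognition_attenuation(spec$gamma2, rel)
  )
  R <- spec$correlations / tcrossprod(lambda)
  diag(R) <- 1
  if (max(abs(R[upper.tri(R)])) > 0.99) {
    stop("disattenuated latent correlation exceeds 0.99: targets inconsistent")
  }
  nearest_psd(R)
}

# log-normal parameters matched to a mean/SD in ml
lognormal_params <- function(mean_ml, sd_ml) {
  sigma2 <- log(1 + (sd_ml / mean_ml)^2)
  list(mu = log(mean_ml) - sigma2 / 2, sigma = sqrt(sigma2))
}

draw_mvn <- function(n, R) {
  L <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R))
  X <- Z %*% L
  colnames(X) <- colnames(R)
  X
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` latent construct vectors from the disattenuated
#' multivariate normal, maps them to regional kinetic truths (clamped at
#' physiologic floors BP_ND >= 0.1, Ki >= 0.005), log-normal lesion volumes
#' with a Fazekas grade derived from fixed volume cuts, demographic
#' variables, and the nine-test cognitive battery (accuracy tests rounded
#' and clamped to their maximum scores; speed tests emitted as
#' `(n_correct, total_rt_ms)` pairs). Optionally simulates the per-subject
#' TAC bundles for both tracers.
#'
#' @param spec a [cohort_spec()].
#' @param tacs logical, also simulate per-subject TAC bundles (default TRUE).
#' @return List with `cohort` (data frame, one row per subject), `truths`
#'   (data frame of simulator ground truth), `tacs` (list of per-subject
#'   bundles or NULL), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), tacs = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  R_lat <- latent_correlations(spec)
  L <- draw_mvn(n, R_lat)

  age <- spec$age_mean + spec$age_sd * L[, "age"]
  sex <- ifelse(L[, "sex"] > 0, "male", "female")
  bmi <- pmax(spec$bmi_mean + spec$bmi_sd * L[, "bmi"], 15)
  hypertension <- stats::rbinom(n, 1, spec$hypertension_prev)

  # DAT regions: shared latent loading sqrt(rho), region uniqueness the rest
  b <- sqrt(spec$dat_region_cor)
  u <- sqrt(1 - spec$dat_region_cor)
  bp_true <- sapply(names(spec$bp_means), function(rg) {
    z <- b * L[, "dat"] + u * stats::rnorm(n)
    pmax(spec$bp_means[[rg]] + spec$bp_sds[[rg]] * z, 0.1)
  })
  colnames(bp_true) <- paste0("bp_", names(spec$bp_means))

  c_load <- sqrt(spec$ki_region_cor)
  c_uni <- sqrt(1 - spec$ki_region_cor)
  ki_true <- sapply(names(spec$ki_means), function(rg) {
    z <- c_load * L[, "maob"] + c_uni * stats::rnorm(n)
    pmax(spec$ki_means[[rg]] + spec$ki_sds[[rg]] * z, 0.005)
  })
  colnames(ki_true) <- paste0("ki_", names(spec$ki_means))

  lp <- lognormal_params(spec$lesion_mean_ml, spec$lesion_sd_ml)
  lesion_ml <- exp(lp$mu + lp$sigma * L[, "lesion"])
  if (!is.null(spec$inject_extreme_lesion_ml)) {
    lesion_ml[which.max(lesion_ml)] <- spec$inject_extreme_lesion_ml
  }
  # Fazekas grade from fixed population-quantile volume cuts (2% below
  # grade 1, 71% below grade 2); grade 3 reserved for volumes > 25 ml
  cuts <- exp(lp$mu + lp$sigma * stats::qnorm(c(0.02, 0.71)))
  fazekas <- findInterval(lesion_ml, c(cuts, 25))

  # cognition: domains load sqrt(gamma2) on the general latent, tests load
  # sqrt(reliability) on their domain
  specs <- cognitive_test_specs()
  gam <- sqrt(spec$gamma2)
  domain_latent <- sapply(c("episodic", "working", "speed"), function(d) {
    gam * L[, "cognition"] + sqrt(1 - spec$gamma2) * stats::rnorm(n)
  })
  acc_mu <- c(
    word_recall = 18, numberword_recall = 5, objectposition_recall = 12,
    letter_updating = 30, number_3back = 75, spatial_updating = 15
  )
  acc_sd <- c(
    word_recall = 5, numberword_recall = 2.5, objectposition_recall = 4,
    letter_updating = 7, number_3back = 15, spatial_updating = 5
  )
  cog <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(specs))) {
    te <- specs$test[i]
    zt <- sqrt(specs$reliability[i]) * domain_latent[, specs$domain[i]] +
      sqrt(1 - specs$reliability[i]) * stats::rnorm(n)
    if (specs$type[i] == "accuracy") {
      cog[[te]] <- pmin(pmax(round(acc_mu[[te]] + acc_sd[[te]] * zt), 0),
                        specs$max_score[i])
    } else {
      rate <- pmax(30 + 6 * zt, 5) # correct responses per minute
      n_corr <- pmax(round(45 + 9 * zt), 5)
      cog[[paste0(te, "_correct")]] <- n_corr
      cog[[paste0(te, "_rt_ms")]] <- n_corr / rate * 60000
    }
  }

  cohort <- data.frame(
    subject_id = sprintf("s%04d", seq_len(n)),
    age = age, sex = sex, bmi = bmi, hypertension = hypertension,
    lesion_ml = lesion_ml, fazekas = fazekas,
    cog,
    stringsAsFactors = FALSE
  )

  if (spec$emulate_missingness) {
    cog_cols <- colnames(cog)
    specs_dom <- stats::setNames(specs$domain, specs$test)
    col_dom <- specs_dom[sub("_(correct|rt_ms)$", "", cog_cols)]
    n_epi_only <- min(10L, n)
    cohort[seq_len(n_epi_only), cog_cols[col_dom != "episodic"]] <- NA
    if (n >= 11L) cohort[11L, cog_cols[col_dom != "working"]] <- NA
  }

  truths <- data.frame(
    subject_id = cohort$subject_id,
    bp_true, ki_true,
    R1 = pmax(stats::rnorm(n, 0.9, 0.05), 0.5),
    k2 = pmax(stats::rnorm(n, 0.15, 0.02), 0.05),
    v0 = pmax(stats::rnorm(n, 1.5, 0.15), 0.5),
    latent_dat = L[, "dat"], latent_maob = L[, "maob"],
    latent_cognition = L[, "cognition"],
    stringsAsFactors = FALSE
  )

  tac_list <- NULL
  if (tacs) {
    pe2i <- pe2i_frame_schedule()
    ded <- ded_frame_schedule()
    miss_pe2i <- if (spec$emulate_missingness && n >= 4) {
      sample(seq_len(n), 4)
    } else {
      integer(0)
    }
    tac_list <- vector("list", n)
    for (i in seq_len(n)) {
      bundle <- list()
      if (!(i %in% miss_pe2i)) {
        ref_r <- make_reference_tac(
          pe2i,
          amplitude = stats::rlnorm(1, log(100), 0.1),
          lambda1 = pmax(stats::rnorm(1, 0.05, 0.005), 0.01),
          lambda2 = pmax(stats::rnorm(1, 1.0, 0.1), 0.3)
        )
        rev_tacs <- lapply(names(spec$bp_means), function(rg) {
          add_frame_noise(
            simulate_reversible_tac(ref_r, truths$R1[i], truths$k2[i],
                                    bp_true[i, paste0("bp_", rg)], region = rg),
            spec$noise_scale
          )
        })
        names(rev_tacs) <- names(spec$bp_means)
        bundle$pe2i <- c(rev_tacs, list(cerebellum = add_frame_noise(ref_r, spec$noise_scale)))
      }
      ref_i <- make_reference_tac(
        ded,
        amplitude = stats::rlnorm(1, log(80), 0.1),
        lambda1 = pmax(stats::rnorm(1, 0.06, 0.005), 0.01),
        lambda2 = pmax(stats::rnorm(1, 0.8, 0.08), 0.3)
      )
      irr_tacs <- list()
      cer <- NULL
      for (rg in names(spec$ki_means)) {
        sim <- simulate_irreversible_tac(ref_i, ki_true[i, paste0("ki_", rg)],
                                         truths$v0[i], region = rg)
        irr_tacs[[rg]] <- add_frame_noise(sim$target, spec$noise_scale)
        cer <- sim$cerebellum
      }
      bundle$ded <- c(irr_tacs, list(cerebellum = add_frame_noise(cer, spec$noise_scale)))
      tac_list[[i]] <- bundle
    }
  }

  list(cohort = cohort, truths = truths, tacs = tac_list, spec = spec)
}
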