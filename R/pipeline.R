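# The four analysis stages as plain functions over the generator's output,
# plus the end-to-end pipeline that writes CSV + JSON sidecars per stage.

#' Fit kinetic models for every subject of a simulated cohort
#'
#' Runs [fit_mrtm()] on the reversible-tracer bundles (caudate, putamen
#' against the cerebellum) and [fit_reference_patlak()] on the
#' irreversible-tracer bundles (all Ki regions against the cerebellum), and
#' appends the fitted `bp_*` and `ki_*` columns to the cohort table.
#' Subjects without a tracer bundle get missing fits.
#'
#' @param sim result of [generate_cohort()] (with `tacs = TRUE`).
#' @param config a [patlak_config()].
#' @return The cohort data frame with fitted kinetic columns added.
#' @export
fit_cohort_kinetics <- function(sim, config = patlak_config()) {
  if (is.null(sim$tacs)) stop("cohort was generated without TACs")
  cohort <- sim$cohort
  n <- nrow(cohort)
  bp_regions <- names(sim$spec$bp_means)
  ki_regions <- names(sim$spec$ki_means)
  for (rg in bp_regions) cohort[[paste0("bp_", rg)]] <- NA_real_
  for (rg in ki_regions) cohort[[paste0("ki_", rg)]] <- NA_real_
  for (i in seq_len(n)) {
    bundle <- sim$tacs[[i]]
    if (!is.null(bundle$pe2i)) {
      cer <- bundle$pe2i$cerebellum
      for (rg in bp_regions) {
        fit <- fit_mrtm(bundle$pe2i[[rg]], cer)
        cohort[i, paste0("bp_", rg)] <- fit$estimate
      }
    }
    if (!is.null(bundle$ded)) {
      cer <- bundle$ded$cerebellum
      for (rg in ki_regions) {
        fit <- fit_reference_patlak(bundle$ded[[rg]], cer, config)
        cohort[i, paste0("ki_", rg)] <- fit$estimate
      }
    }
  }
  cohort
}

#' Build the analysis variables of a fitted cohort
#'
#' Adds the striatal DAT z-composite, the MAO-B first-component factor score
#' (cortex, hippocampus, thalamus; striatum excluded), per-test z-scores
#' (speed tests first converted to correct responses per minute), domain and
#' general-cognition composites, and the log lesion volume.
#'
#' @param cohort data frame with fitted `bp_*`/`ki_*` columns, lesion
#'   volumes, and the nine-test battery.
#' @param require_all_domains passed to [domain_and_general_scores()].
#' @return List: `cohort` (augmented data frame) and `pca` (the
#'   `pca_result`).
#' @export
score_cohort <- function(cohort, require_all_domains = TRUE) {
  cohort$dat_z <- dat_composite(cohort$bp_caudate, cohort$bp_putamen)
  pca <- maob_pca_score(cohort[, c("ki_cortex", "ki_hippocampus", "ki_thalamus")])
  cohort$maob_factor <- pca$scores

  specs <- cognitive_test_specs()
  test_z <- data.frame(row.names = seq_len(nrow(cohort)))
  for (i in seq_len(nrow(specs))) {
    te <- specs$test[i]
    raw <- if (specs$type[i] == "speed") {
      speed_score(cohort[[paste0(te, "_correct")]], cohort[[paste0(te, "_rt_ms")]])
    } else {
      cohort[[te]]
    }
    test_z[[te]] <- zscore(raw)
  }
  dom <- domain_and_general_scores(test_z,
                                   require_all_domains = require_all_domains)
  cohort <- cbind(cohort, dom)
  cohort$log_lesion <- log(cohort$lesion_ml)
  list(cohort = cohort, pca = pca)
}

#' Run the cohort inferential layer
#'
#' Applies the univariate outlier rule (pairwise deletion) to lesion volume
#' and the perceptual-speed domain score, log-transforms lesion volumes,
#' computes the age-adjusted partial correlations among the brain/cognition
#' constructs, and fits the two hierarchical regression ladders: brain
#' correlates of the DAT composite (age + sex, then lesions, then the MAO-B
#' factor) and brain correlates of general cognition (age, then the DAT
#' composite, then lesions + MAO-B factor).
#'
#' @param scored data frame from [score_cohort()].
#' @param outlier_threshold SD threshold of the univariate rule.
#' @return List: `outliers` (reports), `partials`, `dat_model`, `cog_model`,
#'   and the cleaned analysis `data`.
#' @export
analyze_cohort <- function(scored, outlier_threshold = 3.29) {
  d <- scored
  reports <- list(
    lesion_ml = univariate_outliers(d$lesion_ml, outlier_threshold,
                                    variable = "lesion_ml"),
    speed = univariate_outliers(d$speed, outlier_threshold, variable = "speed")
  )
  if (reports$lesion_ml$n_flagged > 0) {
    d$lesion_ml[reports$lesion_ml$flagged] <- NA
  }
  if (reports$speed$n_flagged > 0) {
    flagged <- reports$speed$flagged
    d$speed[flagged] <- NA
    d$general_cognition[flagged] <- NA
  }
  d$log_lesion <- log(d$lesion_ml)

  partials <- list(
    dat_maob = partial_correlation(d$dat_z, d$maob_factor, d$age),
    dat_lesion = partial_correlation(d$dat_z, d$log_lesion, d$age),
    maob_lesion = partial_correlation(d$maob_factor, d$log_lesion, d$age),
    dat_cognition = partial_correlation(d$dat_z, d$general_cognition, d$age),
    age_maob = partial_correlation(d$age, d$maob_factor),
    age_lesion = partial_correlation(d$age, d$log_lesion),
    age_cognition = partial_correlation(d$age, d$general_cognition)
  )

  dat_model <- hierarchical_regression(
    d, "dat_z",
    blocks = list(c("age", "sex"), "log_lesion", "maob_factor")
  )
  cog_model <- hierarchical_regression(
    d, "general_cognition",
    blocks = list("age", "dat_z", c("log_lesion", "maob_factor"))
  )
  list(outliers = reports, partials = partials,
       dat_model = dat_model, cog_model = cog_model, data = d)
}

regression_results_table <- function(model, label) {
  rows <- lapply(seq_along(model$models), function(k) {
    m <- model$models[[k]]
    tb <- m$table
    tb$model <- k
    tb$outcome <- label
    tb$row_type <- "coefficient"
    tb$n <- m$n
    tb$f <- m$f
    tb$adj_r_squared <- m$adj_r_squared
    tb$delta_r2 <- NA_real_
    tb$f_change <- NA_real_
    tb$p_change <- NA_real_
    if (!is.null(m$f_change)) {
      tb <- rbind(tb, data.frame(
        variable = sprintf("delta_R2_model%d_vs_%d", k, k - 1),
        beta = NA, t = NA, partial_r = NA, p = NA, model = k,
        outcome = label, row_type = "r2_change", n = m$n, f = m$f,
        adj_r_squared = m$adj_r_squared, delta_r2 = m$delta_r2,
        f_change = m$f_change, p_change = m$p_change
      ))
    }
    tb
  })
  do.call(rbind, rows)
}

#' Run the full pipeline: simulate, fit, score, analyze
#'
#' Each stage writes its table as CSV plus a JSON sidecar (stage, seed,
#' package version, configuration) under `out_dir`. Deterministic under a
#' fixed spec and seed.
#'
#' @param spec a [cohort_spec()]; its `seed` governs every random draw.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param patlak a [patlak_config()].
#' @param require_all_domains passed to [score_cohort()].
#' @return Invisibly, a list with `cohort`, `scored`, `analysis`, `pca`.
#' @export
run_pipeline <- function(spec = cohort_spec(), out_dir = NULL,
                         patlak = patlak_config(),
                         require_all_domains = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  writing <- !is.null(out_dir)
  if (writing) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) {
    message(sprintf("[petcohort %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }

  log_stage("simulate: n = %d, seed = %d", spec$n_subjects, spec$seed)
  sim <- generate_cohort(spec, tacs = TRUE)
  if (writing) {
    utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truths, file.path(out_dir, "truths.csv"),
                     row.names = FALSE)
    write_sidecar(file.path(out_dir, "simulate.json"), "simulate", spec$seed,
                  list(spec = spec_as_list(spec)))
  }

  log_stage("fit: kinetic models")
  fitted <- fit_cohort_kinetics(sim, patlak)
  if (writing) {
    utils::write.csv(fitted, file.path(out_dir, "fitted.csv"), row.names = FALSE)
    write_sidecar(file.path(out_dir, "fit.json"), "fit", spec$seed,
                  list(lambda_bar = patlak$lambda_bar,
                       fit_frames = range(patlak$fit_frames)))
  }

  log_stage("score: composites")
  sc <- score_cohort(fitted, require_all_domains)
  if (writing) {
    utils::write.csv(sc$cohort, file.path(out_dir, "scored.csv"),
                     row.names = FALSE)
    write_sidecar(file.path(out_dir, "score.json"), "score", spec$seed,
                  list(pca_eigenvalues = sc$pca$eigenvalues,
                       pca_loadings = as.data.frame(sc$pca$loadings),
                       require_all_domains = require_all_domains))
  }

  log_stage("analyze: inferential layer")
  an <- analyze_cohort(sc$cohort)
  if (writing) {
    results <- rbind(
      regression_results_table(an$dat_model, "dat_z"),
      regression_results_table(an$cog_model, "general_cognition")
    )
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    partial_df <- do.call(rbind, lapply(names(an$partials), function(nm) {
      p <- an$partials[[nm]]
      data.frame(pair = nm, r = p$r, p = p$p, df = p$df, n = p$n)
    }))
    utils::write.csv(partial_df, file.path(out_dir, "partials.csv"),
                     row.names = FALSE)
    write_sidecar(file.path(out_dir, "analyze.json"), "analyze", spec$seed,
                  list(outliers_flagged = vapply(an$outliers, function(r)
                    r$n_flagged, integer(1))))
  }
  log_stage("done")
  invisible(list(cohort = sim$cohort, fitted = fitted, scored = sc$cohort,
                 pca = sc$pca, analysis = an))
}
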