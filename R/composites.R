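#' Standardize to z-scores
#'
#' Centers and scales by the complete-case mean and sample (n-1) standard
#' deviation. Missing values stay missing and do not influence the moments.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @return Numeric vector of the same length, mean 0 and SD 1 over complete
#'   cases.
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("zscore needs at least 2 non-missing values")
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) stop("zscore: zero or undefined standard deviation")
  (x - mean(x[ok])) / s
}

#' Striatal DAT composite score
#'
#' Averages caudate and putamen BP_ND per subject on the raw scale, then
#' standardizes the average into a composite z-score. A subject missing one
#' region keeps the other; a subject missing both is missing.
#'
#' @param caudate_bp,putamen_bp paired numeric vectors of regional BP_ND.
#' @return Numeric z-score vector.
#' @export
dat_composite <- function(caudate_bp, putamen_bp) {
  if (length(caudate_bp) != length(putamen_bp)) {
    stop("caudate and putamen vectors must be paired")
  }
  m <- rowMeans(cbind(caudate_bp, putamen_bp), na.rm = TRUE)
  m[is.na(caudate_bp) & is.na(putamen_bp)] <- NA_real_
  zscore(m)
}

#' Perceptual-speed test score
#'
#' Correct responses per minute: `n_correct / total_rt_ms * 60000`.
#'
#' @param n_correct number of correct responses (>= 0).
#' @param total_rt_ms total response time in milliseconds (> 0).
#' @return Responses per minute.
#' @export
speed_score <- function(n_correct, total_rt_ms) {
  if (any(!is.na(total_rt_ms) & total_rt_ms <= 0)) {
    stop("total_rt_ms must be > 0")
  }
  if (any(!is.na(n_correct) & n_correct < 0)) stop("n_correct must be >= 0")
  n_correct / total_rt_ms * 60000
}

#' Principal components of a correlation matrix
#'
#' Eigendecomposition of a correlation matrix with the package's PCA
#' conventions: eigenvalues descending, variance fractions as eigenvalue
#' over variable count, and each loading vector oriented so its mean is
#' positive. This is the closed-form core of [maob_pca_score()] and can be
#' applied directly to a theoretical correlation structure.
#'
#' @param R symmetric correlation matrix (unit diagonal).
#' @return List: `eigenvalues`, `loadings`, `variance_fraction`.
#' @export
pca_from_correlation <- function(R) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-10) stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop("correlation matrix must have unit diagonal")
  eig <- eigen(R, symmetric = TRUE)
  loadings <- eig$vectors
  for (j in seq_len(ncol(loadings))) {
    if (mean(loadings[, j]) < 0) loadings[, j] <- -loadings[, j]
  }
  list(
    eigenvalues = eig$values,
    loadings = loadings,
    variance_fraction = eig$values / sum(eig$values)
  )
}

#' Principal-component factor score for regional MAO-B binding
#'
#' Eigendecomposes the Pearson correlation matrix of regional Ki_ref values
#' (by default cortex, hippocampus, thalamus; the striatum is deliberately
#' not part of this set, to keep the astrocyte factor independent of the
#' striatal DAT composite). Factor scores are the standardized variables
#' projected on the first eigenvector, re-standardized to unit variance.
#' The leading eigenvector's sign is fixed so its mean loading is positive.
#'
#' @param ki_table data frame or matrix, one row per subject, one column per
#'   region (>= 3 complete rows).
#' @return An object of class `pca_result`: `eigenvalues` (descending),
#'   `loadings` (variables x components), `variance_fraction`, and `scores`
#'   (first-component factor score per subject; NA for incomplete rows).
#' @export
maob_pca_score <- function(ki_table) {
  ki <- as.matrix(ki_table)
  if (ncol(ki) < 2) stop("need at least 2 regional variables")
  complete <- stats::complete.cases(ki)
  if (sum(complete) < 3) stop("need at least 3 complete rows")
  if (any(apply(ki[complete, , drop = FALSE], 2, stats::sd) == 0)) {
    stop("constant column: correlation undefined")
  }
  R <- stats::cor(ki[complete, , drop = FALSE])
  if (any(!is.finite(R))) stop("non-finite correlation matrix")
  pc <- pca_from_correlation(R)
  loadings <- pc$loadings
  z <- matrix(NA_real_, nrow(ki), ncol(ki))
  z[complete, ] <- apply(ki[complete, , drop = FALSE], 2, zscore)
  raw <- drop(z %*% loadings[, 1])
  scores <- rep(NA_real_, nrow(ki))
  scores[complete] <- zscore(raw[complete])
  structure(
    list(
      eigenvalues = pc$eigenvalues,
      loadings = loadings,
      variance_fraction = pc$variance_fraction,
      scores = scores
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d variables; PC1 eigenvalue %.2f (%.0f%% of variance)\n",
    length(x$eigenvalues), x$eigenvalues[1], 100 * x$variance_fraction[1]
  ))
  invisible(x)
}

#' Canonical nine-test cognitive battery
#'
#' Three accuracy tests per domain for episodic and working memory (with the
#' battery's maximum scores) and three speed tests scored as correct
#' responses per minute. Reliability values are the battery's published
#' split-half / internal-consistency coefficients and drive the generator's
#' test-level noise.
#'
#' @return Data frame with columns `test`, `domain`, `type`, `max_score`,
#'   `reliability`.
#' @export
cognitive_test_specs <- function() {
  data.frame(
    test = c(
      "word_recall", "numberword_recall", "objectposition_recall",
      "letter_updating", "number_3back", "spatial_updating",
      "letter_comparison", "number_comparison", "figure_comparison"
    ),
    domain = rep(c("episodic", "working", "speed"), each = 3),
    type = rep(c("accuracy", "accuracy", "speed"), each = 3),
    max_score = c(32, 16, 24, 48, 108, 30, NA, NA, NA),
    reliability = c(0.65, 0.58, 0.77, 0.68, 0.91, 0.65, 0.96, 0.95, 0.93),
    stringsAsFactors = FALSE
  )
}

#' Domain and general-cognition composite scores
#'
#' Each domain score is the mean of the available per-test z-scores mapped
#' to that domain; the general score is the mean of the domain scores. A
#' subject with no tests in a domain gets a missing domain score. By default
#' (`require_all_domains = TRUE`) the general score requires all three
#' domains, so subjects tested in only one battery part drop from the
#' general composite; with `FALSE` the general score averages whatever
#' domains remain.
#'
#' @param test_z data frame or matrix of per-test z-scores, one row per
#'   subject, columns named by test.
#' @param domain_map named character vector mapping every test column to a
#'   domain; defaults to the canonical battery of [cognitive_test_specs()].
#' @param require_all_domains logical; see above.
#' @return Data frame with one z-scale column per domain plus
#'   `general_cognition`.
#' @export
domain_and_general_scores <- function(test_z, domain_map = NULL,
                                      require_all_domains = TRUE) {
  test_z <- as.data.frame(test_z)
  if (is.null(domain_map)) {
    specs <- cognitive_test_specs()
    domain_map <- stats::setNames(specs$domain, specs$test)
  }
  unknown <- setdiff(colnames(test_z), names(domain_map))
  if (length(unknown) > 0) {
    stop(sprintf("tests not mapped to any domain: %s", paste(unknown, collapse = ", ")))
  }
  domains <- unique(unname(domain_map[colnames(test_z)]))
  out <- data.frame(row.names = seq_len(nrow(test_z)))
  for (d in domains) {
    cols <- colnames(test_z)[domain_map[colnames(test_z)] == d]
    m <- rowMeans(test_z[, cols, drop = FALSE], na.rm = TRUE)
    m[rowSums(!is.na(test_z[, cols, drop = FALSE])) == 0] <- NA_real_
    out[[d]] <- m
  }
  dm <- as.matrix(out)
  gen <- rowMeans(dm, na.rm = TRUE)
  n_avail <- rowSums(!is.na(dm))
  gen[n_avail == 0] <- NA_real_
  if (require_all_domains) gen[n_avail < length(domains)] <- NA_real_
  out$general_cognition <- gen
  out
}
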