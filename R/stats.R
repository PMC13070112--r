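#' Univariate outlier rule
#'
#' Flags values at least `threshold_sd` sample standard deviations from the
#' mean. Mean and SD are computed from all non-missing values *before* any
#' exclusion; semantics are pairwise deletion (only the flagged variable's
#' value is removed downstream, not the subject). The 3.29-SD default is the
#' two-sided p < 0.001 cut under normality.
#'
#' @param x numeric vector (>= 3 non-missing values).
#' @param threshold_sd flagging threshold in SD units (default 3.29).
#' @param center,scale optional externally supplied mean and SD (e.g. from a
#'   published summary); default to the sample moments of `x`.
#' @param variable variable name recorded in the report.
#' @return An `outlier_report`: rule, threshold, flagged indices, `n_flagged`,
#'   and the z-scores used.
#' @export
univariate_outliers <- function(x, threshold_sd = 3.29, center = NULL,
                                scale = NULL, variable = "x") {
  ok <- !is.na(x)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  if (is.null(center)) center <- mean(x[ok])
  if (is.null(scale)) scale <- stats::sd(x[ok])
  if (!is.finite(scale) || scale == 0) {
    warning("zero standard deviation: no outliers can be flagged")
    z <- rep(0, length(x))
  } else {
    z <- (x - center) / scale
  }
  flagged <- which(!is.na(z) & abs(z) >= threshold_sd)
  structure(
    list(
      variable = variable, rule = "univariate_z", threshold = threshold_sd,
      flagged = flagged, n_flagged = length(flagged), z = z
    ),
    class = "outlier_report"
  )
}

#' Multivariate (Mahalanobis) outlier rule
#'
#' Squared Mahalanobis distances of complete rows against the chi-square
#' upper quantile with `p` degrees of freedom at the given tail probability.
#'
#' @param x numeric matrix or data frame, subjects in rows.
#' @param p_threshold upper-tail probability defining an outlier
#'   (default 0.001).
#' @return An `outlier_report` with the distances in `d2`.
#' @export
mahalanobis_outliers <- function(x, p_threshold = 0.001) {
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  xm <- x[complete, , drop = FALSE]
  p <- ncol(xm)
  if (nrow(xm) <= p + 1) stop("need more complete rows than variables + 1")
  S <- stats::cov(xm)
  if (!is.finite(determinant(S)$modulus) || abs(det(S)) < 1e-300) {
    stop("singular covariance matrix")
  }
  d2_all <- rep(NA_real_, nrow(x))
  d2_all[complete] <- stats::mahalanobis(xm, colMeans(xm), S)
  cut <- stats::qchisq(1 - p_threshold, df = p)
  flagged <- which(!is.na(d2_all) & d2_all > cut)
  structure(
    list(
      variable = paste(colnames(x), collapse = "+"), rule = "mahalanobis",
      threshold = p_threshold, cutoff_d2 = cut,
      flagged = flagged, n_flagged = length(flagged), d2 = d2_all
    ),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %s rule on %s: %d flagged%s\n",
    x$rule, x$variable, x$n_flagged,
    if (x$n_flagged > 0) paste0(" (", paste(x$flagged, collapse = ", "), ")") else ""
  ))
  invisible(x)
}

#' Log-transform skewed lesion volumes
#'
#' Natural log of white-matter lesion volumes (ml), with distribution
#' moments before and after so the normalization can be reported.
#'
#' @param volumes_ml strictly positive volumes in ml (NA allowed).
#' @return List with `log_volumes`, `before` and `after` (each a
#'   [describe_moments()] row).
#' @export
log_lesion_transform <- function(volumes_ml) {
  if (any(!is.na(volumes_ml) & volumes_ml <= 0)) {
    stop("lesion volumes must be > 0")
  }
  lv <- log(volumes_ml)
  list(
    log_volumes = lv,
    before = describe_moments(volumes_ml),
    after = describe_moments(lv)
  )
}

#' Sample moments
#'
#' Mean, sample SD, skewness, excess kurtosis and range. Skewness uses the
#' ordinary moment estimator `m3 / m2^(3/2)`; kurtosis is reported as excess
#' (`m4 / m2^2 - 3`), the convention under which a normal sample is near 0.
#'
#' @param x numeric vector (>= 4 non-missing values for kurtosis).
#' @return One-row data frame: `n`, `mean`, `sd`, `skewness`,
#'   `kurtosis_excess`, `min`, `max`.
#' @export
describe_moments <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  cm <- function(k) mean((x - m)^k)
  data.frame(
    n = n, mean = m, sd = stats::sd(x),
    skewness = if (n >= 3) cm(3) / cm(2)^1.5 else NA_real_,
    kurtosis_excess = if (n >= 4) cm(4) / cm(2)^2 - 3 else NA_real_,
    min = min(x), max = max(x)
  )
}

#' Partial Pearson correlation
#'
#' Correlation between the residuals of `x` and `y` after each is regressed
#' (with intercept) on the covariates, over complete cases. The two-sided p
#' comes from `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates.
#' With no covariates this is the zero-order Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector, matrix or data frame.
#' @return List: `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
  }
  k <- ncol(Z)
  complete <- stats::complete.cases(cbind(x, y, Z))
  n <- sum(complete)
  if (n < k + 3) stop("need at least covariates + 3 complete cases")
  xs <- x[complete]
  ys <- y[complete]
  if (k > 0) {
    Zs <- cbind(1, Z[complete, , drop = FALSE])
    qz <- qr(Zs)
    if (qz$rank < ncol(Zs)) stop("collinear covariates")
    xs <- qr.resid(qz, xs)
    ys <- qr.resid(qz, ys)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("degenerate residuals: zero variance after adjustment")
  }
  r <- stats::cor(xs, ys)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n)
}

#' Hierarchical (blockwise) multiple regression
#'
#' Fits ordinary least squares models on cumulative predictor blocks, on the
#' z-standardized outcome and predictors (binary covariates are 0/1 coded
#' and then standardized, so coefficients are standardized betas throughout).
#' Each cumulative model is fitted on the complete cases of its own variable
#' set; the R-squared-change F test between consecutive blocks refits the
#' smaller model on the larger model's case set so the two are nested on
#' identical data.
#'
#' @param data data frame.
#' @param outcome outcome column name.
#' @param blocks list of character vectors; block k's model uses the union
#'   of blocks 1..k.
#' @return A `hierarchical_regression` object: per-model data frames of
#'   standardized beta, t, partial r and p per predictor, plus model F,
#'   R-squared, adjusted R-squared, df, n, and (from the second block) the
#'   nested comparison `delta_r2`, `f_change`, `df_change`, `p_change`.
#' @export
hierarchical_regression <- function(data, outcome, blocks) {
  stopifnot(is.data.frame(data), length(blocks) >= 1)
  all_vars <- unique(unlist(blocks))
  missing_cols <- setdiff(c(outcome, all_vars), colnames(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("columns not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  numerify <- function(v) {
    if (is.numeric(v)) return(v)
    if (is.logical(v)) return(as.numeric(v))
    f <- as.factor(v)
    if (nlevels(f) != 2) stop("non-numeric predictors must be binary")
    as.numeric(f) - 1
  }
  fit_one <- function(vars, rows) {
    d <- data[rows, , drop = FALSE]
    y <- zscore(numerify(d[[outcome]]))
    X <- sapply(vars, function(v) zscore(numerify(d[[v]])))
    X <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop(sprintf(
        "rank-deficient model: collinearity among {%s}",
        paste(vars, collapse = ", ")
      ))
    }
    beta <- qr.coef(qrX, y)
    res <- qr.resid(qrX, y)
    n <- length(y)
    p <- length(vars)
    rss <- sum(res^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    df_res <- n - p - 1
    sigma2 <- rss / df_res
    XtX_inv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * diag(XtX_inv))
    tvals <- beta / se
    partial_r <- tvals / sqrt(tvals^2 + df_res)
    pvals <- 2 * stats::pt(-abs(tvals), df_res)
    fstat <- if (p > 0) (r2 / p) / ((1 - r2) / df_res) else NA_real_
    list(
      vars = vars, n = n, p = p, rss = rss, r_squared = r2,
      adj_r_squared = 1 - (1 - r2) * (n - 1) / df_res,
      df_res = df_res, f = fstat,
      f_p = stats::pf(fstat, p, df_res, lower.tail = FALSE),
      table = data.frame(
        variable = vars,
        beta = unname(beta[-1]), t = unname(tvals[-1]),
        partial_r = unname(partial_r[-1]), p = unname(pvals[-1]),
        stringsAsFactors = FALSE
      )
    )
  }
  models <- vector("list", length(blocks))
  cum_vars <- character(0)
  for (k in seq_along(blocks)) {
    cum_vars <- unique(c(cum_vars, blocks[[k]]))
    rows <- which(stats::complete.cases(data[, c(outcome, cum_vars), drop = FALSE]))
    if (length(rows) <= length(cum_vars) + 1) {
      stop(sprintf("block %d: need more complete cases than predictors + 1", k))
    }
    m <- fit_one(cum_vars, rows)
    if (k > 1) {
      prev_vars <- models[[k - 1]]$vars
      m_prev <- fit_one(prev_vars, rows) # same case set for a nested test
      q <- m$p - m_prev$p
      delta_r2 <- m$r_squared - m_prev$r_squared
      f_change <- (delta_r2 / q) / ((1 - m$r_squared) / m$df_res)
      m$delta_r2 <- delta_r2
      m$f_change <- f_change
      m$df_change <- c(q, m$df_res)
      m$p_change <- stats::pf(f_change, q, m$df_res, lower.tail = FALSE)
    }
    models[[k]] <- m
  }
  structure(list(outcome = outcome, models = models),
            class = "hierarchical_regression")
}

#' @export
print.hierarchical_regression <- function(x, ...) {
  for (k in seq_along(x$models)) {
    m <- x$models[[k]]
    cat(sprintf(
      "Model %d (n = %d): F = %.1f, p = %.3g, adj R^2 = %.2f\n",
      k, m$n, m$f, m$f_p, m$adj_r_squared
    ))
    tb <- m$table
    for (i in seq_len(nrow(tb))) {
      cat(sprintf(
        "  %-22s beta = %6.2f  t = %5.1f  r = %5.2f  p = %.3g\n",
        tb$variable[i], tb$beta[i], tb$t[i], tb$partial_r[i], tb$p[i]
      ))
    }
    if (!is.null(m$f_change)) {
      cat(sprintf(
        "  dR^2 = %.3f, F(%d,%d) = %.1f, p = %.3g vs model %d\n",
        m$delta_r2, m$df_change[1], m$df_change[2], m$f_change, m$p_change, k - 1
      ))
    }
  }
  invisible(x)
}

#' Two-group comparison
#'
#' Continuous outcomes: two-sample t-test (pooled-variance by default,
#' matching the reported df convention) or, with covariates, a one-way
#' ANCOVA via a linear model whose group term is tested by F. Categorical
#' outcomes: Pearson chi-square without continuity correction.
#'
#' @param values outcome vector (numeric, or a factor/character for the
#'   chi-square path).
#' @param groups grouping vector (two levels for t/ANCOVA).
#' @param covariates optional numeric covariates triggering ANCOVA.
#' @param pooled logical, pooled-variance t-test (default) or Welch.
#' @return List: `method`, `statistic`, `df`, `p`, and group means where
#'   applicable.
#' @export
group_compare <- function(values, groups, covariates = NULL, pooled = TRUE) {
  g <- as.factor(groups)
  if (!is.numeric(values)) {
    tab <- table(values, g)
    if (any(dim(tab) < 2)) stop("chi-square needs at least a 2x2 table")
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(
      method = "chi-square", statistic = unname(ch$statistic),
      df = unname(ch$parameter), p = ch$p.value, table = tab
    ))
  }
  if (nlevels(droplevels(g[!is.na(values)])) != 2) {
    stop("t-test/ANCOVA needs exactly two non-empty groups")
  }
  if (is.null(covariates)) {
    tt <- stats::t.test(values ~ g, var.equal = pooled)
    return(list(
      method = if (pooled) "t (pooled)" else "t (Welch)",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, group_means = tapply(values, g, mean, na.rm = TRUE)
    ))
  }
  Z <- as.matrix(as.data.frame(covariates))
  d <- data.frame(y = values, g = g, Z)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  full <- stats::lm(y ~ ., data = d)
  reduced <- stats::lm(y ~ . - g, data = d)
  an <- stats::anova(reduced, full)
  list(
    method = "ANCOVA", statistic = an$F[2],
    df = c(an$Df[2], full$df.residual), p = an$`Pr(>F)`[2],
    adjusted_means = tapply(stats::resid(reduced) + mean(d$y), d$g, mean)
  )
}

#' Bonferroni adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param family_size number of tests in the family; defaults to
#'   `length(p)`.
#' @return `pmin(1, p * family_size)`.
#' @export
bonferroni_adjust <- function(p, family_size = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (family_size < 1) stop("family_size must be >= 1")
  pmin(1, p * family_size)
}

#' Minimum sample size for an R-squared-change F test
#'
#' Smallest total N at which the noncentral F distribution with
#' `df1 = n_tested`, `df2 = N - n_tested - n_covariates - 1` and
#' noncentrality `lambda = f2 * N` (the common power-software convention;
#' set `ncp_convention = "df"` for `lambda = f2 * (df1 + df2 + 1)`) puts at
#' least `power_target` probability beyond the central-F critical value at
#' `alpha`. Evaluation is exact via the noncentral F distribution.
#'
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param alpha significance level.
#' @param power_target target power in (0, 1).
#' @param n_tested number of tested predictors (df1).
#' @param n_covariates number of additional covariates in the full model.
#' @param ncp_convention `"n"` (lambda = f2 N, default) or `"df"`.
#' @param n_max search ceiling.
#' @return Minimum total N (integer).
#' @export
power_min_n <- function(f2 = 0.15, alpha = 0.05, power_target = 0.80,
                        n_tested = 1, n_covariates = 1,
                        ncp_convention = c("n", "df"), n_max = 100000L) {
  if (!is.finite(f2) || f2 <= 0) stop("f2 must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power_target <= 0 || power_target >= 1) stop("power_target must be in (0, 1)")
  ncp_convention <- match.arg(ncp_convention)
  df1 <- n_tested
  for (N in (n_tested + n_covariates + 2):n_max) {
    df2 <- N - n_tested - n_covariates - 1
    lambda <- if (ncp_convention == "n") f2 * N else f2 * (df1 + df2 + 1)
    pw <- stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
                    ncp = lambda, lower.tail = FALSE)
    if (pw >= power_target) return(N)
  }
  stop("power target unreachable below n_max")
}

#' Achieved power of an R-squared-change F test at a given N
#'
#' Companion to [power_min_n()]; same conventions.
#'
#' @inheritParams power_min_n
#' @param n total sample size.
#' @return Power in (0, 1).
#' @export
power_at_n <- function(n, f2 = 0.15, alpha = 0.05, n_tested = 1,
                       n_covariates = 1, ncp_convention = c("n", "df")) {
  ncp_convention <- match.arg(ncp_convention)
  df1 <- n_tested
  df2 <- n - n_tested - n_covariates - 1
  if (df2 < 1) stop("n too small for the requested model")
  lambda <- if (ncp_convention == "n") f2 * n else f2 * (df1 + df2 + 1)
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
            ncp = lambda, lower.tail = FALSE)
}
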