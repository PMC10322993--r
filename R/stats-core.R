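#' Welch two-sample t-test from summary statistics
#'
#' Unpaired t-test with the Welch-Satterthwaite degrees-of-freedom
#' approximation, computed from group means, standard deviations and sizes
#' (the form needed when only published summary statistics are available).
#' The statistic is group 1 minus group 2.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @return A `test_result` list with elements `statistic` (t), `df`
#'   (fractional), `p_raw` (two-sided), `effect_size` (Cohen's d, pooled SD)
#'   and `n` (`c(n1, n2)`).
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  pooled_sd <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  test_result(statistic = t, df = df, p_raw = p_from_t(t, df),
              effect_size = (mean1 - mean2) / pooled_sd, n = c(n1, n2))
}

#' Two-sided p-value from a t statistic
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (> 0, possibly fractional).
#' @return Two-sided p-value, `2 * P(T >= |t|)`.
#' @export
p_from_t <- function(t, df) {
  stopifnot(is.finite(df), df > 0)
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Cohen's d with pooled standard deviation
#'
#' Classical Cohen's d: difference in means over the pooled SD with
#' `(n1 - 1, n2 - 1)` weighting; no small-sample (Hedges) correction.
#' With the first group the patient group and the second the control group,
#' deficits come out negative.
#'
#' @param values1,values2 Numeric vectors (>= 2 finite values each).
#' @return Cohen's d (group 1 minus group 2).
#' @export
cohens_d <- function(values1, values2) {
  values1 <- values1[is.finite(values1)]
  values2 <- values2[is.finite(values2)]
  n1 <- length(values1); n2 <- length(values2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(values1) + (n2 - 1) * stats::var(values2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(values1) - mean(values2)) / sqrt(sp2)
}

#' Residualize a variable on covariates by OLS
#'
#' Ordinary least-squares residuals of `values` on the covariate matrix plus
#' an intercept. Residuals are exactly orthogonal to every covariate column.
#' `values` may be a matrix; each column is residualized on the same design.
#'
#' @param values Numeric vector or matrix (rows = observations).
#' @param covariates Numeric vector, matrix or data.frame of covariates
#'   aligned with `values`; an intercept is always added.
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, covariates) {
  y <- as.matrix(values)
  x <- cbind(`(intercept)` = 1, as.matrix(covariates))
  stopifnot(nrow(y) == nrow(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("covariate matrix is rank deficient (rank ", qx$rank,
         " < ", ncol(x), " columns including intercept)")
  }
  res <- qr.resid(qx, y)
  if (is.vector(values)) drop(res) else res
}

#' ANCOVA F-test for a two-level group factor
#'
#' Linear model of the measure on the group indicator plus covariates; the
#' reported statistic is the partial F for the group term (the square of its
#' coefficient t), with df = (1, n - p). With age, sex and one global
#' covariate this is df = (1, n - 5).
#'
#' @param measure Numeric response vector.
#' @param group Two-level factor or character vector; the first level of
#'   `factor(group)` is the reference, and the statistic carries the sign of
#'   the non-reference minus reference difference in `effect_size`.
#' @param covariates data.frame or matrix of numeric covariates (may have
#'   zero columns).
#' @return A `test_result` with `statistic` (F for group), `df` (c(1, error
#'   df)), `p_raw`, and `n` per group.
#' @export
ancova_group_effect <- function(measure, group, covariates = NULL) {
  g <- factor(group)
  stopifnot(nlevels(g) == 2L)
  n <- length(measure)
  if (any(table(g) == 0L)) stop("a group is entirely missing")
  x <- if (is.null(covariates) || NCOL(covariates) == 0L) {
    cbind(1, as.numeric(g) - 1)
  } else {
    cov <- as.matrix(covariates)
    # constant covariates carry no information and would alias the
    # intercept; drop them so the model reduces to the plain group contrast
    keep <- apply(cov, 2, function(v) stats::sd(v) > 0)
    cbind(1, as.numeric(g) - 1, cov[, keep, drop = FALSE])
  }
  p <- ncol(x)
  if (n <= p) stop("more model parameters than observations")
  fit <- stats::lm.fit(x, measure)
  if (fit$rank < p) stop("design matrix rank deficient; covariate collinear with group?")
  df2 <- n - p
  sigma2 <- sum(fit$residuals^2) / df2
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- fit$coefficients[2] / se
  test_result(statistic = unname(tval^2), df = c(1, df2),
              p_raw = p_from_t(tval, df2),
              effect_size = NA_real_, n = as.integer(table(g)))
}

#' Pearson correlation with parametric p-value
#'
#' Pairwise-complete Pearson correlation with the usual t-based two-sided
#' p-value, `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Paired numeric vectors; pairs with a missing member are
#'   dropped.
#' @return A `test_result` with `statistic` (r), `df` (n - 2), `p_raw`, `n`
#'   (complete pairs).
#' @export
pearson_with_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(statistic = unname(ct$estimate), df = unname(ct$parameter),
              p_raw = ct$p.value, effect_size = NA_real_, n = n)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Variance-stabilized comparison
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided standard-normal p-value. This is the "Fisher test" used to
#' compare case and control brain-behavior correlations.
#'
#' @param r1,n1 Correlation and sample size in group 1.
#' @param r2,n2 Correlation and sample size in group 2.
#' @return A `test_result` with `statistic` (z), `p_raw`, `n`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  test_result(statistic = z, df = NA_real_,
              p_raw = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              effect_size = NA_real_, n = c(n1, n2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; order-preserving, each adjusted value >= raw,
#' capped at 1. NA values are propagated and excluded from the family size.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Light-weight container for a single test; printed as one line.
test_result <- function(statistic, df, p_raw, effect_size = NA_real_,
                        n = NA_integer_, p_adjusted = NA_real_) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_raw = unname(p_raw), p_adjusted = p_adjusted,
         effect_size = unname(effect_size), n = unname(n)),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- if (all(is.na(x$df))) "" else
    sprintf("(%s)", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("stat%s = %.4g, p = %.4g", df_txt, x$statistic, x$p_raw))
  if (!is.na(x$effect_size)) cat(sprintf(", d = %.3g", x$effect_size))
  cat("\n")
  invisible(x)
}
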