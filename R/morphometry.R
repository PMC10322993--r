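# Build an effect_map data.frame with canonical region order for a measure.
new_effect_map <- function(keys, measure, statistic, df1, df2, p_raw, q, d,
                           n1, n2, contrast, adjustment, covariates) {
  out <- data.frame(
    region = sub("_(lh|rh)$", "", keys),
    hemisphere = sub("^.*_(lh|rh)$", "\\1", keys),
    measure = measure,
    statistic = statistic, df1 = df1, df2 = df2,
    p_raw = p_raw, q = q, d = d, n1 = n1, n2 = n2,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  attr(out, "adjustment") <- adjustment
  attr(out, "covariates") <- covariates
  class(out) <- c("effect_map", "data.frame")
  out
}

map_keys <- function(map) paste0(map$region, "_", map$hemisphere)

contrast_rows <- function(cohort, contrast) {
  stopifnot(length(contrast) == 2, all(contrast %in% cohort$group))
  list(idx1 = which(cohort$group == contrast[1]),
       idx2 = which(cohort$group == contrast[2]))
}

#' Compare global brain measures between two groups
#'
#' Unpaired Welch t-tests on TBV, TSA and WMT with Cohen's d (patient minus
#' control; deficits negative). A global screen: no FDR adjustment.
#'
#' @param cohort A `cohort_table`.
#' @param contrast Character pair `c(patient_group, control_group)`.
#' @return Named list of three `test_result`s (`tbv`, `tsa`, `wmt`).
#' @export
global_comparisons <- function(cohort, contrast) {
  rows <- contrast_rows(cohort, contrast)
  out <- lapply(c(tbv = "tbv_mm3", tsa = "tsa_mm2", wmt = "wmt_mm"),
                function(col) {
    v1 <- cohort[[col]][rows$idx1]
    v2 <- cohort[[col]][rows$idx2]
    welch_t(mean(v1), stats::sd(v1), length(v1),
            mean(v2), stats::sd(v2), length(v2))
  })
  out
}

# Residualize the regional matrix of `measure` on its paired global
# covariate, fit on the pooled contrast subjects (no group term).
residualized_regional <- function(cohort, contrast, measure) {
  rows <- contrast_rows(cohort, contrast)
  idx <- c(rows$idx1, rows$idx2)
  y <- regional_matrix(cohort, measure)[idx, , drop = FALSE]
  g <- cohort[[global_for_measure(measure)]][idx]
  res <- residualize(y, g)
  list(res = res, idx1 = seq_along(rows$idx1),
       idx2 = length(rows$idx1) + seq_along(rows$idx2))
}

#' Cohen's d effect-size map on globally residualized values
#'
#' For every atlas region of one measure family, Cohen's d between the two
#' contrast groups computed on values residualized against the measure's
#' paired global covariate (GMV and subcortical volume on TBV, SA on TSA,
#' CT on WMT), fit on both groups pooled without a group term. This d
#' vector is the object consumed by the convergence and gene-brain stages.
#'
#' @param cohort A `cohort_table`.
#' @param contrast `c(patient_group, control_group)`; d < 0 means patient
#'   deficit.
#' @param measure `"gmv"`, `"sa"`, `"ct"` or `"vol"` (subcortical).
#' @return An `effect_map` data.frame (statistic columns NA; `d` filled).
#' @export
effect_size_map <- function(cohort, contrast, measure) {
  rr <- residualized_regional(cohort, contrast, measure)
  d <- cohens_d_cols(rr$res, rr$idx1, rr$idx2)
  new_effect_map(colnames(rr$res), measure,
                 statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                 p_raw = NA_real_, q = NA_real_, d = d,
                 n1 = length(rr$idx1), n2 = length(rr$idx2),
                 contrast = contrast, adjustment = "residual_d",
                 covariates = global_for_measure(measure))
}

# Shared engine: per-region partial F (or t) for group with covariates,
# vectorized over regions via one QR of the common design matrix.
group_term_tests <- function(y, group01, covariates) {
  x <- cbind(1, group01, as.matrix(covariates))
  n <- nrow(x); p <- ncol(x)
  qx <- qr(x)
  if (qx$rank < p) stop("design matrix rank deficient")
  res <- qr.resid(qx, y)
  df2 <- n - p
  sigma2 <- colSums(res^2) / df2
  xtx_inv <- chol2inv(chol(crossprod(x)))
  coefs <- qr.coef(qx, y)
  tval <- coefs[2, ] / sqrt(sigma2 * xtx_inv[2, 2])
  list(t = tval, df2 = df2)
}

#' Regional ANCOVA map
#'
#' Per-region analysis of covariance: the measure as dependent variable,
#' diagnosis as the between-group factor, and age, sex and the measure's
#' paired global covariate as covariates (error df = n - 5). P-values are
#' BH-FDR adjusted across the regions of this measure family; Cohen's d is
#' taken from the globally residualized values ([effect_size_map()]).
#'
#' @param cohort A `cohort_table`.
#' @param contrast `c(patient_group, control_group)`.
#' @param measure Measure family.
#' @param extra_covariates Extra cohort columns to include (e.g. `"euler"`
#'   for the surface-quality sensitivity analysis).
#' @return An `effect_map` with F statistics, `df1 = 1`, `df2`, `p_raw`,
#'   BH-adjusted `q`, and residualized `d`.
#' @export
ancova_map <- function(cohort, contrast, measure,
                       extra_covariates = character()) {
  rows <- contrast_rows(cohort, contrast)
  idx <- c(rows$idx1, rows$idx2)
  y <- regional_matrix(cohort, measure)[idx, , drop = FALSE]
  group01 <- rep(c(1, 0), c(length(rows$idx1), length(rows$idx2)))
  covars <- cbind(age = cohort$age_years[idx], sex = cohort$sex[idx],
                  global = cohort[[global_for_measure(measure)]][idx])
  for (ec in extra_covariates) covars <- cbind(covars, cohort[[ec]][idx])
  keep <- apply(y, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) warning("degenerate region(s) reported as missing: ",
                          paste(colnames(y)[!keep], collapse = ", "))
  tt <- group_term_tests(y[, keep, drop = FALSE], group01, covars)
  stat <- p <- stats::setNames(rep(NA_real_, ncol(y)), colnames(y))
  stat[keep] <- tt$t^2
  p[keep] <- p_from_t(tt$t, tt$df2)
  dmap <- effect_size_map(cohort, contrast, measure)
  new_effect_map(colnames(y), measure, statistic = stat, df1 = 1,
                 df2 = tt$df2, p_raw = p, q = bh_fdr(p), d = dmap$d,
                 n1 = length(rows$idx1), n2 = length(rows$idx2),
                 contrast = contrast, adjustment = "ancova",
                 covariates = c("age", "sex", global_for_measure(measure),
                                extra_covariates))
}

#' Residualized t-test map (small-subgroup route)
#'
#' For contrasts too small for a stable ANCOVA: residualize every region on
#' the paired global covariate (both groups pooled), then an unpaired
#' pooled-variance t-test on the residuals per region, with BH-FDR across
#' the family and residualized Cohen's d.
#'
#' @inheritParams ancova_map
#' @return An `effect_map` with t statistics (df = n1 + n2 - 2).
#' @export
residual_t_map <- function(cohort, contrast, measure) {
  rr <- residualized_regional(cohort, contrast, measure)
  keep <- apply(rr$res, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) warning("degenerate region(s) reported as missing: ",
                          paste(colnames(rr$res)[!keep], collapse = ", "))
  tt <- pooled_t_cols(rr$res[, keep, drop = FALSE], rr$idx1, rr$idx2)
  stat <- p <- stats::setNames(rep(NA_real_, ncol(rr$res)),
                               colnames(rr$res))
  stat[keep] <- tt$t
  p[keep] <- p_from_t(tt$t, tt$df)
  d <- cohens_d_cols(rr$res, rr$idx1, rr$idx2)
  new_effect_map(colnames(rr$res), measure, statistic = stat,
                 df1 = NA_real_, df2 = tt$df, p_raw = p, q = bh_fdr(p),
                 d = d, n1 = length(rr$idx1), n2 = length(rr$idx2),
                 contrast = contrast, adjustment = "residual_t",
                 covariates = global_for_measure(measure))
}

#' Euler-covariate sensitivity map
#'
#' The ANCOVA map recomputed with the cumulative Euler number (surface
#' reconstruction quality) as an additional covariate; error df drops by
#' one. Comparing this with the primary map region-by-region shows whether
#' results are robust to scan-quality differences between groups.
#'
#' @inheritParams ancova_map
#' @param extra_covariates Additional covariate columns, default `"euler"`.
#' @return An `effect_map`.
#' @export
sensitivity_map <- function(cohort, contrast, measure,
                            extra_covariates = "euler") {
  ancova_map(cohort, contrast, measure, extra_covariates = extra_covariates)
}

#' Write an effect map as a tidy CSV
#'
#' @param map An `effect_map`.
#' @param path File path.
#' @export
write_effect_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
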