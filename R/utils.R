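# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Add-one empirical p-value from a permutation null
#'
#' `(1 + #extreme) / (B + 1)` so the p-value is never zero. Sidedness
#' `"greater"` counts `null >= observed`, `"less"` counts `null <=
#' observed`, `"two"` counts `|null| >= |observed|`, and `"directional"`
#' picks `"greater"` when the observed statistic is non-negative and
#' `"less"` otherwise.
#'
#' @param null Numeric vector of null statistics.
#' @param observed Observed statistic.
#' @param sided One of `"greater"`, `"less"`, `"two"`, `"directional"`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(null, observed,
                        sided = c("greater", "less", "two", "directional")) {
  sided <- match.arg(sided)
  null <- null[is.finite(null)]
  if (sided == "directional") sided <- if (observed >= 0) "greater" else "less"
  extreme <- switch(sided,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two = sum(abs(null) >= abs(observed)))
  (1 + extreme) / (length(null) + 1)
}

# Constructor for permutation/rotation null records.
null_distribution <- function(method, values, observed, sided, seed,
                              n_permutations = length(values)) {
  structure(
    list(method = method, values = values, observed = observed,
         n_permutations = n_permutations,
         p_empirical = empirical_p(values, observed, sided),
         sided = sided, seed = seed),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s null: observed = %.4g, B = %d, empirical p = %.4g (%s)\n",
              x$method, x$observed, x$n_permutations, x$p_empirical, x$sided))
  invisible(x)
}

# Column-wise Cohen's d (pooled SD) of Y rows in group1 vs group2 indices.
cohens_d_cols <- function(y, idx1, idx2) {
  y1 <- y[idx1, , drop = FALSE]
  y2 <- y[idx2, , drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- colMeans(y1); m2 <- colMeans(y2)
  v1 <- colSums(sweep(y1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(y2, 2, m2)^2) / (n2 - 1)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

# Column-wise pooled-variance two-sample t (group1 minus group2).
pooled_t_cols <- function(y, idx1, idx2) {
  d <- cohens_d_cols(y, idx1, idx2)
  n1 <- length(idx1); n2 <- length(idx2)
  t <- d / sqrt(1 / n1 + 1 / n2)
  list(t = t, df = n1 + n2 - 2)
}
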