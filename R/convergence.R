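#' Spatial correlation between two effect-size maps
#'
#' Pearson correlation of the region-wise Cohen's d vectors of two maps
#' over their shared, pairwise-complete regions. Maps must cover the same
#' measure family and atlas.
#'
#' @param mapA,mapB `effect_map` objects.
#' @return Pearson r.
#' @export
map_correlation <- function(mapA, mapB) {
  kA <- map_keys(mapA); kB <- map_keys(mapB)
  shared <- intersect(kA, kB)
  dA <- mapA$d[match(shared, kA)]
  dB <- mapB$d[match(shared, kB)]
  ok <- is.finite(dA) & is.finite(dB)
  if (sum(ok) < 3) stop("fewer than 3 shared complete regions")
  stats::cor(dA[ok], dB[ok])
}

# Residual-route d map as a bare vector, for use inside permutation loops:
# residualize Y rows (patients + reference) on g, pooled fit, then d.
fast_residual_d <- function(y, g, idx_pat, idx_ref) {
  rows <- c(idx_pat, idx_ref)
  x <- cbind(1, g[rows])
  res <- qr.resid(qr(x), y[rows, , drop = FALSE])
  cohens_d_cols(res, seq_along(idx_pat),
                length(idx_pat) + seq_along(idx_ref))
}

#' Permutation test for convergence of two genotype effect maps
#'
#' The observed statistic is the Pearson correlation between the two
#' subgroups' residual-route effect-size maps (each versus the fixed
#' reference group). The null is built by randomly reassigning patient
#' subjects to pseudo-subgroups of the original sizes (reference subjects
#' never move), recomputing both maps and their correlation per
#' permutation. One-sided (upper tail) add-one empirical p: convergence
#' means the observed correlation exceeds null expectation.
#'
#' @param cohort A `cohort_table`.
#' @param subgroupA,subgroupB Patient group labels (e.g. `"PTPN11"`,
#'   `"SOS1"`).
#' @param reference Control group label, untouched by permutation.
#' @param measure Measure family (`"gmv"`, `"sa"`, `"ct"`, `"vol"`).
#' @param n_perm Number of label permutations (study-scale default 2000).
#' @param seed Integer seed for the permutation stream.
#' @param permute Permutation scope. `"all_subjects"` (default) reassigns
#'   genetic status across the whole cohort including the reference group,
#'   so the null describes maps computed from uninformative labels — the
#'   construction under which convergent genotype maps can exceed every
#'   null value. `"patients_only"` reshuffles labels within the patient
#'   pool with the reference fixed; its null mixes the two genotypes'
#'   effects into both pseudo-maps and is a test of subgroup
#'   *difference*, not convergence (see the methods vignette).
#' @return A `null_distribution` (method `"label_permutation"`) with the
#'   observed r, null values, and empirical p.
#' @export
convergence_test <- function(cohort, subgroupA = "PTPN11",
                             subgroupB = "SOS1", reference = "TD",
                             measure = "gmv", n_perm = 2000L, seed = 1L,
                             permute = c("all_subjects", "patients_only")) {
  permute <- match.arg(permute)
  stopifnot(subgroupA != subgroupB)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse empirical p")
  idxA <- which(cohort$group == subgroupA)
  idxB <- which(cohort$group == subgroupB)
  idxR <- which(cohort$group == reference)
  stopifnot(length(idxA) >= 2, length(idxB) >= 2, length(idxR) >= 2)
  y <- regional_matrix(cohort, measure)
  g <- cohort[[global_for_measure(measure)]]
  dA <- fast_residual_d(y, g, idxA, idxR)
  dB <- fast_residual_d(y, g, idxB, idxR)
  observed <- stats::cor(dA, dB)
  nA <- length(idxA); nB <- length(idxB)
  null_r <- with_seed(seed, {
    if (permute == "patients_only") {
      pool <- c(idxA, idxB)
      vapply(seq_len(n_perm), function(b) {
        perm <- sample(pool)
        stats::cor(fast_residual_d(y, g, perm[seq_len(nA)], idxR),
                   fast_residual_d(y, g, perm[-seq_len(nA)], idxR))
      }, numeric(1))
    } else {
      pool <- c(idxA, idxB, idxR)
      vapply(seq_len(n_perm), function(b) {
        perm <- sample(pool)
        pA <- perm[seq_len(nA)]
        pB <- perm[nA + seq_len(nB)]
        pR <- perm[-seq_len(nA + nB)]
        stats::cor(fast_residual_d(y, g, pA, pR),
                   fast_residual_d(y, g, pB, pR))
      }, numeric(1))
    }
  })
  nd <- null_distribution("label_permutation", null_r, observed,
                          sided = "greater", seed = seed)
  nd$measure <- measure
  nd$subgroups <- c(subgroupA, subgroupB)
  nd$permute <- permute
  nd
}
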