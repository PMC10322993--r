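#' Striatal composite volumes
#'
#' Left and right striatal composites: caudate + putamen + pallidum volume
#' per side. A missing structure makes that side's composite missing.
#'
#' @param cohort A `cohort_table`.
#' @return data.frame with `subject_id`, `left_mm3`, `right_mm3`.
#' @export
striatal_composite <- function(cohort) {
  parts <- c("caudate", "putamen", "pallidum")
  side_sum <- function(hemi) {
    cols <- paste0(parts, "_", hemi, "_vol")
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols))
      stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
    rowSums(cohort[, cols])
  }
  data.frame(subject_id = cohort$subject_id,
             left_mm3 = side_sum("lh"), right_mm3 = side_sum("rh"),
             stringsAsFactors = FALSE)
}

# Brain variables available for brain-behavior analysis.
brain_variable <- function(cohort, name) {
  comp <- striatal_composite(cohort)
  switch(name,
    striatal_left = comp$left_mm3,
    striatal_right = comp$right_mm3,
    hippocampus_left = cohort$hippocampus_lh_vol,
    hippocampus_right = cohort$hippocampus_rh_vol,
    {
      if (!name %in% names(cohort)) stop("unknown brain variable: ", name)
      cohort[[name]]
    })
}

#' Default hypothesis-driven brain-behavior pair set
#'
#' Striatal composites against attention and inhibition scores,
#' hippocampal volumes against memory scores.
#'
#' @return data.frame with columns `brain_var`, `score`.
#' @export
default_pair_set <- function() {
  rbind(
    expand.grid(brain_var = c("striatal_left", "striatal_right"),
                score = c("auditory_attention", "inhibition"),
                stringsAsFactors = FALSE),
    expand.grid(brain_var = c("hippocampus_left", "hippocampus_right"),
                score = c("memory_faces_delayed",
                          "narrative_memory_free_recall"),
                stringsAsFactors = FALSE))
}

#' Within-group brain-behavior correlations
#'
#' For each group and each (brain variable, score) pair: optionally
#' residualize the brain variable on TBV within the group, then Pearson r
#' with parametric p over pairwise-complete subjects. The score is never
#' adjusted; per-pair n follows pairwise completeness.
#'
#' @param cohort A `cohort_table`.
#' @param behavior A `behavior_table`.
#' @param pairs data.frame with `brain_var` and `score` columns (default
#'   [default_pair_set()]).
#' @param groups Groups to analyse (default all in the cohort).
#' @param adjust_global Residualize the brain variable on TBV within group
#'   (default TRUE).
#' @return Tidy data.frame: `group`, `brain_var`, `score`, `adjusted`,
#'   `n`, `r`, `p`. Pairs with fewer than 4 complete subjects get NA.
#' @export
group_correlations <- function(cohort, behavior, pairs = default_pair_set(),
                               groups = unique(cohort$group),
                               adjust_global = TRUE) {
  stopifnot(all(behavior$subject_id %in% cohort$subject_id))
  behavior <- behavior[match(cohort$subject_id, behavior$subject_id), ]
  out <- list()
  for (g in groups) {
    in_g <- cohort$group == g
    for (i in seq_len(nrow(pairs))) {
      bv <- pairs$brain_var[i]; sc <- pairs$score[i]
      brain <- brain_variable(cohort, bv)[in_g]
      score <- behavior[[sc]][in_g]
      tbv <- cohort$tbv_mm3[in_g]
      ok <- is.finite(brain) & is.finite(score) & is.finite(tbv)
      row <- data.frame(group = g, brain_var = bv, score = sc,
                        adjusted = adjust_global, n = sum(ok),
                        r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
      if (sum(ok) >= 4) {
        b <- brain[ok]
        if (adjust_global) b <- residualize(b, tbv[ok])
        tr <- pearson_with_p(b, score[ok])
        row$r <- tr$statistic
        row$p <- tr$p_raw
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Between-group comparison of brain-behavior correlations
#'
#' Fisher r-to-z comparison of the two groups' correlations for every
#' matching (brain variable, score) pair, with BH-FDR across exactly the
#' pairs tested in this call. Pairs with a degenerate correlation (|r| =
#' 1) or missing estimate are excluded with a warning.
#'
#' @param group_results Output of [group_correlations()].
#' @param groups Length-2 character: `c(patient_group, control_group)`;
#'   z > 0 means the patient correlation is larger.
#' @return data.frame: `brain_var`, `score`, `r1`, `n1`, `r2`, `n2`, `z`,
#'   `p_raw`, `q`.
#' @export
between_group_tests <- function(group_results,
                                groups = c("PTPN11", "TD")) {
  g1 <- group_results[group_results$group == groups[1], ]
  g2 <- group_results[group_results$group == groups[2], ]
  m <- merge(g1, g2, by = c("brain_var", "score"),
             suffixes = c("1", "2"))
  usable <- is.finite(m$r1) & is.finite(m$r2) &
    abs(m$r1) < 1 & abs(m$r2) < 1 & m$n1 > 3 & m$n2 > 3
  if (any(!usable))
    warning(sum(!usable), " pair(s) excluded (degenerate or missing r)")
  m <- m[usable, ]
  z <- p <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    tr <- fisher_z_compare(m$r1[i], m$n1[i], m$r2[i], m$n2[i])
    z[i] <- tr$statistic
    p[i] <- tr$p_raw
  }
  out <- data.frame(brain_var = m$brain_var, score = m$score,
                    r1 = m$r1, n1 = m$n1, r2 = m$r2, n2 = m$n2,
                    z = z, p_raw = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
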