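#' Default behavior-score specification
#'
#' Four neuropsychological scaled scores (attention, inhibition, two memory
#' scores) with per-group means and SDs matching the demographic table of
#' the emulated cohort, a programmed within-group correlation between the
#' inhibition score and striatal volume (negative in the larger patient
#' group, weakly positive in controls), and per-test missingness emulating
#' age-restricted administration.
#'
#' @return A list of score specifications, each with elements `name`,
#'   `mean`, `sd`, `r` (named per group; correlation with the standardized
#'   striatal composite), `n_missing` (named per group).
#' @export
default_behavior_spec <- function() {
  list(
    list(name = "auditory_attention",
         mean = c(PTPN11 = 8.21, SOS1 = 9.80, TD = 10.18),
         sd = c(PTPN11 = 3.19, SOS1 = 3.52, TD = 2.89),
         r = c(PTPN11 = 0, SOS1 = 0, TD = 0),
         n_missing = c(PTPN11 = 2L, SOS1 = 0L, TD = 1L)),
    list(name = "inhibition",
         mean = c(PTPN11 = 7.51, SOS1 = 7.70, TD = 10.51),
         sd = c(PTPN11 = 3.36, SOS1 = 3.83, TD = 2.99),
         r = c(PTPN11 = -0.42, SOS1 = 0, TD = 0.23),
         n_missing = c(PTPN11 = 1L, SOS1 = 0L, TD = 1L)),
    list(name = "memory_faces_delayed",
         mean = c(PTPN11 = 8.72, SOS1 = 10.30, TD = 10.97),
         sd = c(PTPN11 = 3.05, SOS1 = 3.83, TD = 2.29),
         r = c(PTPN11 = 0, SOS1 = 0, TD = 0),
         n_missing = c(PTPN11 = 1L, SOS1 = 0L, TD = 1L)),
    list(name = "narrative_memory_free_recall",
         mean = c(PTPN11 = 9.38, SOS1 = 9.30, TD = 11.89),
         sd = c(PTPN11 = 3.02, SOS1 = 3.55, TD = 2.89),
         r = c(PTPN11 = 0, SOS1 = 0, TD = 0),
         n_missing = c(PTPN11 = 1L, SOS1 = 0L, TD = 2L)))
}

#' Simulate behavior scores coupled to striatal volume
#'
#' Per-group scores with specified mean and SD and a specified within-group
#' Pearson correlation to the subject's bilateral striatal composite
#' (caudate + putamen + pallidum, both sides), achieved by the conditional
#' Gaussian construction
#' `score = mean + sd * (r * z_striatum + sqrt(1 - r^2) * z_noise)`.
#' Because one latent draw drives both sides, left- and right-composite
#' correlations are both close to the target. Missing scores are assigned
#' at random per group.
#'
#' @param config A [sim_config()]; `config$behavior_spec` defines the
#'   scores.
#' @param cohort The matching [simulate_cohort()] output.
#' @return A data.frame of class `behavior_table` with `subject_id`,
#'   `group`, and one column per score (NA = missing).
#' @export
simulate_behavior <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "cohort_table"))
  comp <- striatal_composite(cohort)
  bilat <- comp$left_mm3 + comp$right_mm3
  with_seed(config$seed + 202L, {
    out <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                      stringsAsFactors = FALSE)
    for (spec in config$behavior_spec) {
      score <- rep(NA_real_, nrow(cohort))
      for (g in unique(cohort$group)) {
        idx <- which(cohort$group == g)
        rho <- spec$r[[g]]
        if (is.null(rho) || is.na(rho)) rho <- 0
        if (abs(rho) >= 1) stop("target correlation must satisfy |r| < 1")
        zb <- as.numeric(scale(bilat[idx]))
        ze <- stats::rnorm(length(idx))
        score[idx] <- spec$mean[[g]] +
          spec$sd[[g]] * (rho * zb + sqrt(1 - rho^2) * ze)
        nm <- spec$n_missing[[g]]
        if (!is.null(nm) && nm > 0) {
          drop_idx <- sample(idx, min(nm, length(idx)))
          score[drop_idx] <- NA_real_
        }
      }
      out[[spec$name]] <- score
    }
    class(out) <- c("behavior_table", "data.frame")
    out
  })
}

#' Write / read a behavior table as CSV
#'
#' @param behavior A `behavior_table`.
#' @param path File path.
#' @return `read_behavior` returns the `behavior_table`.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(as.data.frame(behavior), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("behavior_table", "data.frame")
  out
}
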