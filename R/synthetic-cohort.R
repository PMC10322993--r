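#' Simulation configuration
#'
#' Builds the configuration object consumed by all four synthetic-data
#' generators. Defaults emulate the study conditions of a two-genotype
#' Noonan syndrome cohort versus typically developing (TD) controls:
#' group sizes 30 (PTPN11) / 10 (SOS1) / 40 (TD), global-measure deficits
#' of d = (-0.98, -0.55, -1.04) for TBV/TSA/WMT in the larger patient group
#' and (-0.49, -0.44, -0.70) in the smaller, and a six-donor transcriptome
#' with right-hemisphere samples for only two donors.
#'
#' Regional values are generated as a region-specific share of the
#' subject's global measure plus independent Gaussian noise, so global
#' adjustment is non-trivial; the programmed per-region `d` is the effect
#' expressed on the globally residualized scale. Regional measures are
#' conditionally independent given the global measure.
#'
#' @param group_sizes Named integer vector of subjects per group; the last
#'   name is treated as the control group.
#' @param effect_map `NULL` (no regional effects) or a data.frame with
#'   columns `region`, `hemisphere` ("lh"/"rh"), `measure`
#'   ("gmv","sa","ct","vol"), `d`, and optionally `group` (default: applies
#'   to every patient group).
#' @param global_effects Named list: per patient group a numeric vector
#'   `c(tbv=, tsa=, wmt=)` of programmed Cohen's d on the global measures.
#' @param covariate_slopes List with `age` and `sex` vectors of slopes on
#'   the global measures (units per year, units per male).
#' @param noise_sd Named fractions of the regional baseline used as the
#'   residual SD per measure family.
#' @param behavior_spec List of score specifications; see
#'   [simulate_behavior()].
#' @param transcriptome_spec List; see [simulate_transcriptome()].
#' @param sphere_spec List with `n_vertices` and `n_parcels_per_hemisphere`.
#' @param euler_spec Named list per group of `c(mean=, sd=)` for the
#'   cumulative Euler number (surface quality index).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c(PTPN11 = 30L, SOS1 = 10L, TD = 40L),
                       effect_map = NULL,
                       global_effects = list(
                         PTPN11 = c(tbv = -0.98, tsa = -0.55, wmt = -1.04),
                         SOS1 = c(tbv = -0.49, tsa = -0.44, wmt = -0.70)),
                       covariate_slopes = list(
                         age = c(tbv = 9000, tsa = 2500, wmt = -0.01),
                         sex = c(tbv = 40000, tsa = 12000, wmt = 0.02)),
                       noise_sd = c(gmv = 0.12, sa = 0.12, ct = 0.05,
                                    vol = 0.12),
                       behavior_spec = default_behavior_spec(),
                       transcriptome_spec = list(),
                       sphere_spec = list(),
                       euler_spec = list(
                         PTPN11 = c(mean = -178.25, sd = 73.57),
                         SOS1 = c(mean = -178.25, sd = 73.57),
                         TD = c(mean = -145.25, sd = 56.90)),
                       seed = 1L) {
  stopifnot(length(group_sizes) >= 2, !is.null(names(group_sizes)),
            all(group_sizes > 0))
  if (!is.null(effect_map)) {
    stopifnot(is.data.frame(effect_map),
              all(c("region", "hemisphere", "measure", "d") %in%
                    names(effect_map)),
              all(is.finite(effect_map$d)))
    known <- c(dk_regions(), subcortical_structures())
    bad <- setdiff(effect_map$region, known)
    if (length(bad)) stop("effect_map references unknown region(s): ",
                          paste(bad, collapse = ", "))
    stopifnot(all(effect_map$hemisphere %in% c("lh", "rh")),
              all(effect_map$measure %in% measure_families()))
  }
  tx <- utils::modifyList(list(
    n_donors = 6L, samples_per_donor = 100L, n_genes = 200L,
    probes_per_gene = 2L, brain_gene_fraction = 0.3, length_scale = 0.4,
    n_centers = 24L, probe_offset_sd = 0.3, noise_sd = 0.3,
    baseline_mean = 7, baseline_sd = 1, n_right_donors = 2L,
    target_gene = "GENE_TARGET", target_r = NA_real_, target_map = NULL),
    transcriptome_spec)
  stopifnot(tx$probes_per_gene >= 1, tx$n_donors >= 1,
            tx$brain_gene_fraction > 0, tx$brain_gene_fraction < 1)
  sph <- utils::modifyList(
    list(n_vertices = 2000L, n_parcels_per_hemisphere = 34L), sphere_spec)
  stopifnot(sph$n_vertices >= 10 * sph$n_parcels_per_hemisphere)
  structure(
    list(group_sizes = group_sizes, effect_map = effect_map,
         global_effects = global_effects, covariate_slopes = covariate_slopes,
         noise_sd = noise_sd, behavior_spec = behavior_spec,
         transcriptome_spec = tx, sphere_spec = sph,
         euler_spec = euler_spec, seed = as.integer(seed)),
    class = "sim_config")
}

# Demographic priors per group (age mean/sd in years, proportion male),
# following the cohort description; unknown groups fall back to controls.
group_demographics <- function(group) {
  switch(group,
    PTPN11 = list(age = c(8.70, 2.31), range = c(4.4, 12.3), p_male = 11 / 30),
    SOS1 = list(age = c(7.93, 1.53), range = c(5.7, 10.4), p_male = 4 / 10),
    list(age = c(9.24, 1.62), range = c(4.0, 12.0), p_male = 13 / 40))
}

# Global-measure population parameters (children, mm^3 / mm^2 / mm).
global_params <- function() {
  list(mean = c(tbv = 600000, tsa = 180000, wmt = 2.60),
       sd = c(tbv = 55000, tsa = 16000, wmt = 0.10))
}

# Deterministic regional baselines: region r's expected value when the
# subject's global measure equals its population mean. A fixed quasi-random
# weight sequence spreads region sizes without an RNG draw.
regional_baselines <- function(measure) {
  keys <- bilateral_regions()
  i <- seq_along(keys)
  w <- 0.5 + ((i * 37) %% 67) / 67
  gp <- global_params()
  b <- switch(measure,
    gmv = gp$mean["tbv"] * 0.7 * w / sum(w),
    sa = gp$mean["tsa"] * w / sum(w),
    ct = 2.2 + 0.8 * ((i * 17) %% 67) / 67,
    stop("unknown cortical measure: ", measure))
  names(b) <- keys
  b
}

subcortical_baselines <- function() {
  per_side <- c(caudate = 4000, putamen = 5500, pallidum = 1800,
                hippocampus = 4200)
  b <- rep(per_side, times = 2)
  names(b) <- bilateral_regions(subcortical_structures())
  b
}

# Programmed d per bilateral-region key for one group and measure family.
programmed_d <- function(config, group, measure, keys) {
  d <- stats::setNames(rep(0, length(keys)), keys)
  em <- config$effect_map
  if (is.null(em)) return(d)
  if (!"group" %in% names(em)) em$group <- NA_character_
  em <- em[em$measure == measure & (is.na(em$group) | em$group == group), ,
           drop = FALSE]
  if (!nrow(em)) return(d)
  k <- paste0(em$region, "_", em$hemisphere)
  d[k] <- em$d
  d
}

control_group <- function(config) {
  names(config$group_sizes)[length(config$group_sizes)]
}

#' Simulate a subject-level cohort table
#'
#' Generates one row per subject with demographics, Euler number, global
#' measures (TBV, TSA, WMT), 68 cortical regional values for each of GMV,
#' SA and CT, and 8 subcortical volumes. Patient-group regional effects are
#' injected on the residual scale: region value = baseline x
#' (global / global mean) + d x sigma_region x 1\[patient\] + noise, so the
#' programmed d is what a globally adjusted analysis should recover.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `cohort_table`; columns `subject_id`,
#'   `group`, `age_years`, `sex` (0 female / 1 male), `euler`, `tbv_mm3`,
#'   `tsa_mm2`, `wmt_mm`, then `<region>_<lh|rh>_<gmv|sa|ct>` and
#'   `<structure>_<lh|rh>_vol`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    gp <- global_params()
    ctrl <- control_group(config)
    rows <- list()
    for (g in names(config$group_sizes)) {
      n <- config$group_sizes[[g]]
      dem <- group_demographics(g)
      age <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          a <- stats::rnorm(1, dem$age[1], dem$age[2])
          if (a >= dem$range[1] && a <= dem$range[2]) break
        }
        age[i] <- a
      }
      sex <- stats::rbinom(n, 1, dem$p_male)
      eu <- config$euler_spec[[g]]
      if (is.null(eu)) eu <- c(mean = -150, sd = 60)
      euler <- round(stats::rnorm(n, eu[["mean"]], eu[["sd"]]))
      is_pat <- g != ctrl
      d_glob <- if (is_pat && !is.null(config$global_effects[[g]]))
        config$global_effects[[g]] else c(tbv = 0, tsa = 0, wmt = 0)
      glob <- sapply(c("tbv", "tsa", "wmt"), function(m) {
        gp$mean[[m]] +
          config$covariate_slopes$age[[m]] * (age - 9) +
          config$covariate_slopes$sex[[m]] * sex +
          d_glob[[m]] * gp$sd[[m]] +
          stats::rnorm(n, 0, gp$sd[[m]])
      })
      reg <- list()
      for (meas in c("gmv", "sa", "ct")) {
        b <- regional_baselines(meas)
        gname <- c(tbv_mm3 = "tbv", tsa_mm2 = "tsa",
                   wmt_mm = "wmt")[[global_for_measure(meas)]]
        sigma <- config$noise_sd[[meas]] * b
        dv <- if (is_pat)
          programmed_d(config, g, meas, names(b)) else 0 * b
        scale_g <- glob[, gname] / gp$mean[[gname]]
        vals <- outer(scale_g, b) +
          matrix(dv * sigma, n, length(b), byrow = TRUE) +
          sweep(matrix(stats::rnorm(n * length(b)), n, length(b)), 2, sigma,
                `*`)
        colnames(vals) <- paste0(names(b), "_", meas)
        reg[[meas]] <- vals
      }
      b <- subcortical_baselines()
      sigma <- config$noise_sd[["vol"]] * b
      dv <- if (is_pat) programmed_d(config, g, "vol", names(b)) else 0 * b
      scale_g <- glob[, "tbv"] / gp$mean[["tbv"]]
      sub_vals <- outer(scale_g, b) +
        matrix(dv * sigma, n, length(b), byrow = TRUE) +
        sweep(matrix(stats::rnorm(n * length(b)), n, length(b)), 2, sigma, `*`)
      colnames(sub_vals) <- paste0(names(b), "_vol")
      rows[[g]] <- data.frame(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g, age_years = age, sex = sex, euler = as.integer(euler),
        tbv_mm3 = glob[, "tbv"], tsa_mm2 = glob[, "tsa"],
        wmt_mm = glob[, "wmt"],
        reg$gmv, reg$sa, reg$ct, sub_vals,
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "control_group") <- ctrl
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

# Extract the subjects-x-regions matrix for one measure family.
regional_matrix <- function(cohort, measure) {
  keys <- if (measure == "vol") bilateral_regions(subcortical_structures())
          else bilateral_regions()
  cols <- paste0(keys, "_", measure)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(cohort[, cols])
  colnames(m) <- keys
  m
}

#' Write / read a cohort table as CSV
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `read_cohort` returns the `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
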