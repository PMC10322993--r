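#' Demonstration effect map with study-scale programmed effects
#'
#' Subcortical volume effects follow the printed case-control Cohen's d
#' pattern of the emulated study (bilateral caudate, putamen, pallidum
#' deficits and a right hippocampal deficit in the larger patient group;
#' bilateral pallidum deficits with weaker striatal involvement in the
#' smaller group), plus a shared smooth cortical pattern for the three
#' cortical measures so the two genotype maps spatially converge.
#'
#' @param cortical_scale Multipliers of the shared cortical pattern per
#'   group.
#' @return data.frame suitable as `effect_map` input to [sim_config()].
#' @export
demo_effect_map <- function(cortical_scale = c(PTPN11 = 1, SOS1 = 0.8)) {
  sub <- data.frame(
    group = c(rep("PTPN11", 7), rep("SOS1", 6)),
    region = c("caudate", "caudate", "putamen", "putamen", "pallidum",
               "pallidum", "hippocampus",
               "pallidum", "pallidum", "caudate", "caudate", "putamen",
               "putamen"),
    hemisphere = c("lh", "rh", "lh", "rh", "lh", "rh", "rh",
                   "lh", "rh", "lh", "rh", "lh", "rh"),
    measure = "vol",
    d = c(-0.70, -1.03, -0.86, -0.91, -0.91, -0.88, -0.53,
          -0.80, -1.03, -0.30, -0.30, -0.30, -0.30),
    stringsAsFactors = FALSE)
  # shared cortical pattern: smooth deterministic signed pattern over the
  # canonical region order, strongest around motor/occipital indices
  keys <- bilateral_regions()
  i <- seq_along(keys)
  pattern <- 0.6 * sin(i * 0.45) - 0.2
  cort <- do.call(rbind, lapply(names(cortical_scale), function(g) {
    do.call(rbind, lapply(c("gmv", "sa", "ct"), function(m) {
      data.frame(group = g,
                 region = sub("_(lh|rh)$", "", keys),
                 hemisphere = sub("^.*_(lh|rh)$", "\\1", keys),
                 measure = m, d = pattern * cortical_scale[[g]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rbind(sub, cort)
}

#' Demonstration simulation configuration
#'
#' A [sim_config()] at the emulated study's conditions with the
#' [demo_effect_map()] programmed effects.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
demo_sim_config <- function(seed = 1L, ...) {
  sim_config(effect_map = demo_effect_map(), seed = seed, ...)
}

default_run_config <- function() {
  list(seed = NULL, output_dir = "morphogene_run",
       stages = c("simulate", "effects", "convergence", "genebrain",
                  "behavior"),
       n_perm = 500L, n_rot = 200L, n_gene_draws = 1000L,
       gene_subset = "all", sided = "directional", adjust_global = TRUE,
       target_r = 0.6, schema_version = "1")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return Named list merged over the defaults; unknown keys are rejected
#'   and a missing `seed` is an error.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else stop("config must be .json or .yaml/.yml")
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  if (is.null(out$seed)) stop("config must set an explicit seed")
  out$seed <- as.integer(out$seed)
  out
}

#' Run the full pipeline from a configuration
#'
#' Executes the selected stages in dependency order — simulate (cohort,
#' sphere, transcriptome, behavior), regional effects (ANCOVA and residual
#' routes plus Euler sensitivity), subgroup convergence permutation tests,
#' gene-brain association with spin and gene nulls, brain-behavior
#' decoupling tests — writing every output table plus a JSON manifest to
#' the output directory. Identical configuration gives byte-identical
#' outputs.
#'
#' @param config A config list (see [read_run_config()]) or a path to a
#'   JSON/YAML config file.
#' @param output_dir Optional override of `config$output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  else {
    defaults <- default_run_config()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    config <- utils::modifyList(defaults, config)
    if (is.null(config$seed)) stop("config must set an explicit seed")
  }
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # the manifest describes the computation, not where it landed, so the
  # same config writes byte-identical manifests into any directory
  manifest <- list(schema_version = config$schema_version,
                   config = config[setdiff(names(config), "output_dir")],
                   stages = list())
  sim <- demo_sim_config(seed = config$seed)
  cohort <- simulate_cohort(sim)
  sphere <- simulate_sphere_parcellation(sim)
  sa_map <- effect_size_map(cohort, c("PTPN11", "TD"), "sa")
  sim$transcriptome_spec$target_r <- config$target_r
  sim$transcriptome_spec$target_map <- map_d_vector(sa_map)
  expr_data <- simulate_transcriptome(sim, sphere)
  behavior <- simulate_behavior(sim, cohort)

  if ("simulate" %in% config$stages) {
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_sphere(sphere, file.path(out_dir, "sphere.csv"))
    write_behavior(behavior, file.path(out_dir, "behavior.csv"))
    write_expression(expr_data, file.path(out_dir, "expression"))
    manifest$stages$simulate <- list(
      n_subjects = nrow(cohort), n_vertices = nrow(sphere),
      n_probes = nrow(expr_data$values),
      n_samples = ncol(expr_data$values))
  }
  if ("effects" %in% config$stages) {
    glob <- global_comparisons(cohort, c("PTPN11", "TD"))
    maps <- list()
    for (m in measure_families()) {
      maps[[paste0("PTPN11_", m)]] <-
        ancova_map(cohort, c("PTPN11", "TD"), m)
      maps[[paste0("PTPN11_", m, "_euler")]] <-
        sensitivity_map(cohort, c("PTPN11", "TD"), m)
      maps[[paste0("SOS1_", m)]] <-
        residual_t_map(cohort, c("SOS1", "TD"), m)
    }
    for (nm in names(maps))
      write_effect_map(maps[[nm]],
                       file.path(out_dir, paste0("map_", nm, ".csv")))
    manifest$stages$effects <- list(
      global_p = sapply(glob, `[[`, "p_raw"),
      global_d = sapply(glob, `[[`, "effect_size"),
      n_maps = length(maps))
  }
  if ("convergence" %in% config$stages) {
    conv <- lapply(stats::setNames(nm = measure_families()), function(m)
      convergence_test(cohort, "PTPN11", "SOS1", "TD", m,
                       n_perm = config$n_perm, seed = config$seed + 11L))
    for (m in names(conv)) {
      utils::write.csv(
        data.frame(null_r = conv[[m]]$values),
        file.path(out_dir, paste0("convergence_null_", m, ".csv")),
        row.names = FALSE)
    }
    manifest$stages$convergence <- lapply(conv, function(x)
      list(observed_r = x$observed, p = x$p_empirical,
           n_perm = x$n_permutations))
  }
  if ("genebrain" %in% config$stages) {
    gene <- sim$transcriptome_spec$target_gene
    expr <- region_expression(expr_data, sphere, gene)
    write_region_expression(expr,
                            file.path(out_dir, "region_expression.csv"))
    assoc <- associate(expr, sa_map)
    lobes <- lobe_profile(expr, sa_map)
    spin <- spatial_null(expr_data, sphere, gene, sa_map,
                         n_rot = config$n_rot, seed = config$seed + 21L,
                         sided = config$sided)
    rand <- gene_null(expr_data, sphere, gene, sa_map, subset = "all",
                      n_draws = config$n_gene_draws,
                      seed = config$seed + 22L, sided = config$sided)
    brain <- gene_null(expr_data, sphere, gene, sa_map, subset = "brain",
                       n_draws = config$n_gene_draws,
                       seed = config$seed + 23L, sided = config$sided)
    manifest$stages$genebrain <- list(
      r = assoc$r, p_parametric = assoc$p_parametric,
      p_spatial = spin$p_empirical, p_random_gene = rand$p_empirical,
      p_brain_gene = brain$p_empirical,
      lobe_r = sapply(lobes, `[[`, "r"))
  }
  if ("behavior" %in% config$stages) {
    for (adj in c(TRUE, FALSE)) {
      gc <- group_correlations(cohort, behavior,
                               groups = c("PTPN11", "TD"),
                               adjust_global = adj)
      bt <- between_group_tests(gc)
      tag <- if (adj) "adjusted" else "raw"
      utils::write.csv(gc, file.path(
        out_dir, paste0("behavior_correlations_", tag, ".csv")),
        row.names = FALSE)
      utils::write.csv(bt, file.path(
        out_dir, paste0("behavior_comparisons_", tag, ".csv")),
        row.names = FALSE)
      if (adj) manifest$stages$behavior <- list(
        inhibition_left_z =
          bt$z[bt$brain_var == "striatal_left" & bt$score == "inhibition"],
        n_pairs = nrow(bt))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# nearest known region name, for validation diagnostics
suggest_region <- function(name) {
  known <- c(dk_regions(), subcortical_structures())
  d <- utils::adist(name, known)
  known[which.min(d)]
}

#' Validate pipeline input tables
#'
#' Header, type, range and invariant checks for the file schemas the
#' pipeline consumes. Problems are collected, not thrown; unreadable files
#' become error entries.
#'
#' @param paths Named list with any of `cohort`, `behavior`, `sphere`,
#'   `expression` (directory).
#' @return data.frame with `file`, `level` (`"error"`/`"warning"`),
#'   `message`; zero rows when everything passes.
#' @export
validate_tables <- function(paths) {
  report <- list()
  note <- function(file, level, message)
    report[[length(report) + 1L]] <<- data.frame(
      file = file, level = level, message = message,
      stringsAsFactors = FALSE)
  if (!is.null(paths$cohort)) {
    tab <- tryCatch(utils::read.csv(paths$cohort, check.names = FALSE),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      note(paths$cohort, "error", conditionMessage(tab))
    } else {
      required <- c("subject_id", "group", "age_years", "sex", "euler",
                    "tbv_mm3", "tsa_mm2", "wmt_mm")
      miss <- setdiff(required, names(tab))
      if (length(miss))
        note(paths$cohort, "error",
             paste("missing columns:", paste(miss, collapse = ", ")))
      value_cols <- grep("_(lh|rh)_(gmv|sa|ct|vol)$", names(tab),
                         value = TRUE)
      regs <- unique(sub("_(lh|rh)_(gmv|sa|ct|vol)$", "", value_cols))
      known <- c(dk_regions(), subcortical_structures())
      for (r in setdiff(regs, known))
        note(paths$cohort, "error",
             sprintf("unknown region '%s'; did you mean '%s'?", r,
                     suggest_region(r)))
      for (col in value_cols) {
        v <- tab[[col]]
        if (any(is.finite(v) & v <= 0))
          note(paths$cohort, "error",
               paste("non-positive values in", col))
      }
      if (length(miss) == 0 && "age_years" %in% names(tab) &&
          any(tab$age_years <= 0, na.rm = TRUE))
        note(paths$cohort, "error", "non-positive ages")
      extra <- setdiff(names(tab), c(required, value_cols))
      if (length(extra))
        note(paths$cohort, "warning",
             paste("extra columns ignored:", paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(paths$behavior)) {
    tab <- tryCatch(utils::read.csv(paths$behavior), error = function(e) e)
    if (inherits(tab, "error")) note(paths$behavior, "error",
                                     conditionMessage(tab))
    else if (!"subject_id" %in% names(tab))
      note(paths$behavior, "error", "missing subject_id column")
  }
  if (!is.null(paths$sphere)) {
    tab <- tryCatch(utils::read.csv(paths$sphere), error = function(e) e)
    if (inherits(tab, "error")) {
      note(paths$sphere, "error", conditionMessage(tab))
    } else {
      need <- c("vertex_id", "x", "y", "z", "hemisphere", "parcel_label")
      miss <- setdiff(need, names(tab))
      if (length(miss))
        note(paths$sphere, "error",
             paste("missing columns:", paste(miss, collapse = ", ")))
      else {
        norms <- sqrt(tab$x^2 + tab$y^2 + tab$z^2)
        if (any(abs(norms - 1) > 1e-6))
          note(paths$sphere, "error", "vertices not on the unit sphere")
      }
    }
  }
  if (!is.null(paths$expression)) {
    for (f in c("SampleAnnot.csv", "Expression.csv", "ProbeMap.csv")) {
      fp <- file.path(paths$expression, f)
      if (!file.exists(fp)) note(fp, "error", "file not found")
    }
  }
  if (!length(report))
    return(data.frame(file = character(), level = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}
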