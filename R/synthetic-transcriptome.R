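# Smooth latent field on the sphere: kernel-weighted sum of random bumps.
# Returns a function mapping an m x 3 coordinate matrix to m field values.
smooth_field <- function(n_centers, length_scale) {
  centers <- matrix(stats::rnorm(3 * n_centers), n_centers, 3)
  centers <- centers / sqrt(rowSums(centers^2))
  weights <- stats::rnorm(n_centers)
  function(coords) {
    dots <- coords %*% t(centers)
    dots[dots > 1] <- 1
    dots[dots < -1] <- -1
    ang <- acos(dots)
    drop(exp(-ang^2 / (2 * length_scale^2)) %*% weights)
  }
}

#' Simulate an atlas-style transcriptome
#'
#' Emulates a multi-donor postmortem microarray dataset: samples placed at
#' random vertices of the spherical parcellation (right-hemisphere samples
#' only for a donor subset, default 2 of 6), per-gene spatially smooth
#' latent expression fields on the sphere, and probe values = latent value
#' + per-probe offset + noise. Expression fields are homotopic: a
#' right-hemisphere sample is evaluated at its mirrored left-hemisphere
#' position.
#'
#' A designated target gene can be programmed with a region-level
#' correlation to a supplied map: its latent field is piecewise constant
#' within parcels, `rho * z(map) + sqrt(1 - rho^2) * z(noise)` across
#' regions, so the aggregated region vector correlates with the map at
#' about `rho`.
#'
#' @param config A [sim_config()]; `config$transcriptome_spec` fields:
#'   `n_donors`, `samples_per_donor`, `n_genes`, `probes_per_gene`,
#'   `brain_gene_fraction`, `length_scale` (radians), `n_centers`,
#'   `probe_offset_sd`, `noise_sd`, `baseline_mean`, `baseline_sd`,
#'   `n_right_donors`, `target_gene`, `target_r`, `target_map` (named
#'   vector over `<region>_<hemi>` keys).
#' @param sphere A [simulate_sphere_parcellation()] output.
#' @return A list of class `expression_dataset` with elements `samples`
#'   (donor_id, sample_id, x, y, z, hemisphere, vertex_id), `values`
#'   (probe x sample matrix of log2 intensities), `probes` (probe_id,
#'   gene), `genes` (gene, is_brain, is_target), and `latent` (gene x
#'   sample matrix before probe effects, for diagnostics).
#' @export
simulate_transcriptome <- function(config, sphere) {
  stopifnot(inherits(config, "sim_config"),
            inherits(sphere, "sphere_parcellation"))
  tx <- config$transcriptome_spec
  if (tx$probes_per_gene < 1) stop("probes_per_gene must be >= 1")
  lh_coords <- sphere_vertices(sphere, "lh")
  lh_labels <- sphere_labels(sphere, "lh")
  n_v <- nrow(lh_coords)
  with_seed(config$seed + 404L, {
    genes <- c(tx$target_gene,
               sprintf("GENE_%04d", seq_len(tx$n_genes - 1L)))
    n_brain <- max(1L, round(tx$brain_gene_fraction * tx$n_genes))
    is_brain <- genes %in% c(tx$target_gene,
                             sample(genes[-1], n_brain - 1L))
    # sample placement
    samp <- list()
    for (d in seq_len(tx$n_donors)) {
      n_s <- tx$samples_per_donor
      has_rh <- d <= tx$n_right_donors
      n_rh <- if (has_rh) n_s %/% 2L else 0L
      vidx <- sample.int(n_v, n_s, replace = n_s > n_v)
      hemi <- c(rep("lh", n_s - n_rh), rep("rh", n_rh))
      coords <- lh_coords[vidx, , drop = FALSE]
      coords[hemi == "rh", 1] <- -coords[hemi == "rh", 1]
      samp[[d]] <- data.frame(
        donor_id = sprintf("donor_%02d", d),
        sample_id = sprintf("S%02d_%04d", d, seq_len(n_s)),
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        hemisphere = hemi, vertex_id = vidx, stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, samp)
    rownames(samples) <- NULL
    n_samples <- nrow(samples)
    # evaluate latent fields at mirrored-to-left sample positions
    eval_coords <- as.matrix(samples[, c("x", "y", "z")])
    eval_coords[samples$hemisphere == "rh", 1] <-
      -eval_coords[samples$hemisphere == "rh", 1]
    latent <- matrix(NA_real_, tx$n_genes, n_samples,
                     dimnames = list(genes, samples$sample_id))
    baselines <- stats::rnorm(tx$n_genes, tx$baseline_mean, tx$baseline_sd)
    region_keys <- paste0(lh_labels[samples$vertex_id], "_",
                          samples$hemisphere)
    for (g in seq_len(tx$n_genes)) {
      programmed <- g == 1L && is.finite(tx$target_r) &&
        !is.null(tx$target_map)
      if (programmed) {
        map <- tx$target_map
        mz <- as.numeric(scale(map))
        names(mz) <- names(map)
        resid_z <- stats::rnorm(length(map))
        names(resid_z) <- names(map)
        reg_val <- tx$target_r * mz +
          sqrt(1 - tx$target_r^2) * resid_z
        latent[g, ] <- baselines[g] + reg_val[region_keys]
      } else {
        f <- smooth_field(tx$n_centers, tx$length_scale)
        vals <- f(eval_coords)
        latent[g, ] <- baselines[g] +
          (vals - mean(vals)) / max(stats::sd(vals), 1e-12)
      }
    }
    probes <- data.frame(
      probe_id = sprintf("PROBE_%05d", seq_len(tx$n_genes *
                                                 tx$probes_per_gene)),
      gene = rep(genes, each = tx$probes_per_gene),
      stringsAsFactors = FALSE)
    offsets <- stats::rnorm(nrow(probes), 0, tx$probe_offset_sd)
    values <- latent[rep(seq_len(tx$n_genes), each = tx$probes_per_gene), ,
                     drop = FALSE] +
      offsets +
      matrix(stats::rnorm(nrow(probes) * n_samples, 0, tx$noise_sd),
             nrow(probes), n_samples)
    dimnames(values) <- list(probes$probe_id, samples$sample_id)
    structure(
      list(samples = samples, values = values, probes = probes,
           genes = data.frame(gene = genes, is_brain = is_brain,
                              is_target = genes == tx$target_gene,
                              stringsAsFactors = FALSE),
           latent = latent),
      class = "expression_dataset")
  })
}

#' Write / read an expression dataset as a three-file CSV layout
#'
#' Mirrors the layout of public microarray atlas downloads: a sample
#' annotation table, a probe x sample expression matrix, and a probe-to-gene
#' map (with the brain-gene flag).
#'
#' @param dataset An `expression_dataset`.
#' @param dir Directory for `SampleAnnot.csv`, `Expression.csv`,
#'   `ProbeMap.csv`.
#' @return `read_expression` returns the `expression_dataset` (without the
#'   `latent` diagnostic element).
#' @export
write_expression <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$samples, file.path(dir, "SampleAnnot.csv"),
                   row.names = FALSE)
  expr <- data.frame(probe_id = rownames(dataset$values), dataset$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(expr, file.path(dir, "Expression.csv"), row.names = FALSE)
  pm <- merge(dataset$probes, dataset$genes, by = "gene", sort = FALSE)
  pm <- pm[match(dataset$probes$probe_id, pm$probe_id),
           c("probe_id", "gene", "is_brain", "is_target")]
  utils::write.csv(pm, file.path(dir, "ProbeMap.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_expression
#' @export
read_expression <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "SampleAnnot.csv"),
                             stringsAsFactors = FALSE)
  expr <- utils::read.csv(file.path(dir, "Expression.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(expr[, -1, drop = FALSE])
  rownames(values) <- expr$probe_id
  pm <- utils::read.csv(file.path(dir, "ProbeMap.csv"),
                        stringsAsFactors = FALSE)
  genes <- unique(pm[, c("gene", "is_brain", "is_target")])
  structure(
    list(samples = samples, values = values,
         probes = pm[, c("probe_id", "gene")],
         genes = genes[order(match(genes$gene, pm$gene)), ],
         latent = NULL),
    class = "expression_dataset")
}
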