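map_d_vector <- function(map) {
  if (is.data.frame(map)) stats::setNames(map$d, map_keys(map)) else map
}

scope_regions <- function(scope, lobe_map = dk_lobes()) {
  if (scope == "whole_brain") return(bilateral_regions())
  regions <- names(lobe_map)[lobe_map == scope]
  if (!length(regions)) stop("unknown scope: ", scope)
  bilateral_regions(regions)
}

#' Correlate regional gene expression with an effect-size map
#'
#' Pearson correlation (with parametric p) between a region-level
#' expression vector and the region-wise Cohen's d of an effect-size map,
#' over pairwise-complete regions, optionally restricted to one lobe.
#'
#' @param expr A `region_expression` or named vector over
#'   `<region>_<hemi>` keys.
#' @param map An `effect_map` or named d vector.
#' @param scope `"whole_brain"` or a lobe name (`"frontal"`, `"parietal"`,
#'   `"temporal"`, `"occipital"`).
#' @param lobe_map Region-to-lobe assignment (default [dk_lobes()]).
#' @return List of class `association_result`: `scope`, `r`,
#'   `p_parametric`, `n_regions`, `nulls` (empty; filled by the null-model
#'   functions).
#' @export
associate <- function(expr, map, scope = "whole_brain",
                      lobe_map = dk_lobes()) {
  e <- expression_vector(expr)
  d <- map_d_vector(map)
  keys <- intersect(scope_regions(scope, lobe_map), intersect(names(e),
                                                              names(d)))
  x <- e[keys]; y <- d[keys]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 complete regions in scope ", scope)
  tr <- pearson_with_p(x[ok], y[ok])
  structure(list(scope = scope, r = tr$statistic,
                 p_parametric = tr$p_raw, n_regions = tr$n,
                 nulls = list()),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: r = %.3f, parametric p = %.4g (n = %d regions)\n",
              x$scope, x$r, x$p_parametric, x$n_regions))
  for (nd in x$nulls) print(nd)
  invisible(x)
}

#' Draw a uniform random rotation of the sphere
#'
#' A 3x3 proper rotation matrix distributed uniformly (Haar measure) over
#' SO(3), via QR decomposition of a Gaussian matrix with sign correction;
#' determinant +1. The mirrored operator used for the opposite hemisphere
#' is `M %*% R %*% M` with `M = diag(-1, 1, 1)`.
#'
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qrd <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qrd)
    q <- q %*% diag(sign(diag(qr.R(qrd))))
    if (det(q) < 0) q[, 3] <- -q[, 3]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

mirror_rotation <- function(rotation) {
  m <- diag(c(-1, 1, 1))
  m %*% rotation %*% m
}

# Precompute everything the spin loop needs: per-sample expression for the
# gene, sample coordinates mirrored into the left-hemisphere frame, left
# vertex coordinates, integer parcel codes, and the fixed map vector.
spin_precompute <- function(dataset, sphere, gene, map) {
  coords <- as.matrix(dataset$samples[, c("x", "y", "z")])
  rh <- dataset$samples$hemisphere == "rh"
  coords[rh, 1] <- -coords[rh, 1]
  labels <- sphere_labels(sphere, "lh")
  parcels <- unique(labels)
  regions <- c(paste0(parcels, "_lh"), paste0(parcels, "_rh"))
  n_p <- length(parcels)
  donor_int <- as.integer(factor(dataset$samples$donor_id))
  d_full <- map_d_vector(map)
  list(expr = unname(collapse_probes(dataset, gene)),
       coords = coords,
       tverts = t(sphere_vertices(sphere, "lh")),
       parcel_idx = match(labels, parcels),
       rh_off = ifelse(rh, n_p, 0L),
       n_parcels = n_p,
       donor_int = donor_int,
       n_donors = max(donor_int),
       within = "mean",
       d = unname(d_full[regions]),
       regions = regions)
}

# Correlation of the rebuilt expression vector with the map under one
# rotation of the parcellation (identity rotation = observed statistic).
# Mirrored-in-lh-frame sample coordinates make one pass serve both
# hemispheres: for a left rotation R and its mirrored right counterpart,
# the nearest rotated vertex of any sample is argmax_v (s_lh' R v).
spin_r_once <- function(pre, rotation, within_donor = "mean") {
  scores <- (pre$coords %*% rotation) %*% pre$tverts
  nearest <- max.col(scores, ties.method = "first")
  region <- pre$parcel_idx[nearest] + pre$rh_off
  n_reg <- 2L * pre$n_parcels
  # donor-x-region linear code doubles as an index into the stage-1 matrix
  code <- pre$donor_int + (region - 1L) * pre$n_donors
  stage1 <- matrix(NA_real_, pre$n_donors, n_reg)
  if (within_donor == "mean") {
    sums <- rowsum(pre$expr, code)
    stage1[as.integer(rownames(sums))] <-
      sums / tabulate(code, nbins = pre$n_donors * n_reg)[
        as.integer(rownames(sums))]
  } else {
    med <- tapply(pre$expr, code, stats::median)
    stage1[as.integer(names(med))] <- med
  }
  v <- apply(stage1, 2, stats::median, na.rm = TRUE)
  ok <- !is.na(v) & is.finite(pre$d)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(v[ok], pre$d[ok])
}

#' Spatial spin null for a gene-brain correlation
#'
#' Tests a gene-expression-vs-effect-size correlation against a null that
#' preserves the spatial autocorrelation of the data: the labeled spherical
#' parcellation is rigidly rotated (uniform random rotations; the right
#' hemisphere uses the mirrored rotation to preserve homotopy), samples are
#' reassigned to the rotated parcels, the full probe-to-region aggregation
#' chain is re-run, and the rebuilt expression vector is correlated with
#' the fixed map. Rotations leaving fewer than 3 complete regions are
#' redrawn (count recorded). Add-one empirical p, one-sided in the
#' direction of the observed r by default.
#'
#' @param dataset An `expression_dataset`.
#' @param sphere A `sphere_parcellation`.
#' @param gene Target gene.
#' @param map An `effect_map` (fixed across rotations).
#' @param n_rot Number of rotations (study-scale default 1000).
#' @param seed Integer seed.
#' @param sided Sidedness of the empirical p (default `"directional"`).
#' @param within_donor Stage-1 aggregation statistic.
#' @param rotations Optional list of rotation matrices to use instead of
#'   random draws (e.g. `list(diag(3))` reproduces the observed r).
#' @return A `null_distribution` (method `"spatial_spin"`) with extra
#'   element `n_redrawn`.
#' @export
spatial_null <- function(dataset, sphere, gene, map, n_rot = 1000L,
                         seed = 1L, sided = "directional",
                         within_donor = "mean", rotations = NULL) {
  pre <- spin_precompute(dataset, sphere, gene, map)
  observed <- spin_r_once(pre, diag(3), within_donor)
  n_redrawn <- 0L
  values <- with_seed(seed, {
    if (!is.null(rotations)) {
      vapply(rotations, function(rot) spin_r_once(pre, rot, within_donor),
             numeric(1))
    } else {
      vapply(seq_len(n_rot), function(b) {
        repeat {
          r <- spin_r_once(pre, random_rotation(), within_donor)
          if (is.finite(r)) return(r)
          n_redrawn <<- n_redrawn + 1L
          if (n_redrawn > 100L * n_rot) stop("too many degenerate rotations")
        }
      }, numeric(1))
    }
  })
  nd <- null_distribution("spatial_spin", values, observed, sided = sided,
                          seed = seed)
  nd$n_redrawn <- n_redrawn
  nd$gene <- gene
  nd
}

#' Random-gene and brain-gene nulls for a gene-brain correlation
#'
#' Tests whether the observed correlation is specific to the target gene:
#' same-sized gene sets are drawn without replacement from the gene pool
#' (all genes, or the brain-overexpressed subset), each drawn set's
#' region-level expression vectors (built by the full aggregation chain and
#' cached per gene) are averaged and correlated with the fixed map.
#' The target gene is excluded from the pool by default. Add-one empirical
#' p with configurable sidedness.
#'
#' @inheritParams spatial_null
#' @param subset `"all"` (null-random-gene) or `"brain"`
#'   (null-brain-gene).
#' @param set_size Genes per draw (default 1, matching a single-gene
#'   observation).
#' @param n_draws Number of gene-set draws (study-scale default 10000).
#' @param exclude_target Drop the target gene from the pool (default TRUE).
#' @return A `null_distribution` (method `"random_gene"` or
#'   `"brain_gene"`).
#' @export
gene_null <- function(dataset, sphere, gene, map,
                      subset = c("all", "brain"), set_size = 1L,
                      n_draws = 10000L, seed = 1L, sided = "directional",
                      within_donor = "mean", exclude_target = TRUE) {
  subset <- match.arg(subset)
  asg <- assign_samples(dataset, sphere)
  regions <- bilateral_regions()
  cache <- if (within_donor == "mean") {
    region_matrix_all_genes(dataset, asg$region, regions)
  } else {
    t(vapply(dataset$genes$gene, function(g)
      aggregate_vector(collapse_probes(dataset, g), asg$region,
                       dataset$samples$donor_id, regions, within_donor),
      numeric(length(regions))))
  }
  d <- map_d_vector(map)[regions]
  cor_with_map <- function(v) {
    ok <- is.finite(v) & is.finite(d)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(v[ok], d[ok])
  }
  if (!gene %in% rownames(cache)) stop("gene not in dataset: ", gene)
  observed <- cor_with_map(cache[gene, ])
  pool <- dataset$genes$gene
  if (subset == "brain") pool <- pool[dataset$genes$is_brain]
  if (exclude_target) pool <- setdiff(pool, gene)
  if (length(pool) <= set_size) stop("gene pool too small for set size")
  values <- with_seed(seed, {
    vapply(seq_len(n_draws), function(b) {
      drawn <- sample(pool, set_size)
      v <- if (set_size == 1L) cache[drawn, ]
           else colMeans(cache[drawn, , drop = FALSE])
      cor_with_map(v)
    }, numeric(1))
  })
  nd <- null_distribution(
    if (subset == "all") "random_gene" else "brain_gene",
    values, observed, sided = sided, seed = seed)
  nd$gene <- gene
  nd
}

#' Lobe-wise gene-brain association profile
#'
#' One [associate()] result per lobe; no cross-lobe multiplicity
#' adjustment.
#'
#' @inheritParams associate
#' @return Named list of `association_result`s, one per lobe.
#' @export
lobe_profile <- function(expr, map, lobe_map = dk_lobes()) {
  lobes <- unique(unname(lobe_map))
  stats::setNames(lapply(lobes, function(l)
    associate(expr, map, scope = l, lobe_map = lobe_map)), lobes)
}
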