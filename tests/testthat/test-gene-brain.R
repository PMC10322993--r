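test_that("random rotations are proper isometries", {
  set.seed(66)
  for (i in 1:20) {
    r <- random_rotation()
    expect_equal(det(r), 1, tolerance = 1e-10)
    expect_equal(crossprod(r), diag(3), tolerance = 1e-10)
  }
  # pairwise angular distances preserved
  pts <- matrix(rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  r <- random_rotation(seed = 8)
  expect_equal(tcrossprod(pts %*% r), tcrossprod(pts), tolerance = 1e-10)
  expect_identical(random_rotation(seed = 4), random_rotation(seed = 4))
})

test_that("rotated images of a fixed vector cover the sphere uniformly", {
  set.seed(10)
  imgs <- t(vapply(1:4000, function(i) drop(c(0, 0, 1) %*% random_rotation()),
                   numeric(3)))
  # octant occupancy: 8 equal-probability cells
  oct <- 1 + (imgs[, 1] > 0) + 2 * (imgs[, 2] > 0) + 4 * (imgs[, 3] > 0)
  counts <- tabulate(oct, 8)
  expect_gt(chisq.test(counts)$p.value, 0.001)
  # z-coordinate of a uniform point on the sphere is uniform on [-1, 1]
  expect_lt(suppressWarnings(
    ks.test(imgs[, 3], "punif", -1, 1)$statistic), 0.05)
})

test_that("associate is exact on self-correlation and affine-invariant", {
  co <- simulate_cohort(demo_sim_config(seed = 3))
  m <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  d_vec <- stats::setNames(m$d, paste0(m$region, "_", m$hemisphere))
  expect_equal(associate(d_vec, m)$r, 1)
  expect_equal(associate(3 * d_vec - 11, m)$r, 1, tolerance = 1e-12)
  expect_equal(associate(-d_vec, m)$r, -1)
  expect_error(associate(d_vec[1:2], m))
})

test_that("identity rotation reproduces the observed correlation exactly", {
  cfg <- sim_config(seed = 14, transcriptome_spec = list(
    n_genes = 6L, samples_per_donor = 40L))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  co <- simulate_cohort(demo_sim_config(seed = 14))
  m <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  obs <- associate(region_expression(tx, sph, "GENE_TARGET"), m)$r
  sn <- spatial_null(tx, sph, "GENE_TARGET", m,
                     rotations = list(diag(3), random_rotation(seed = 2)))
  expect_equal(sn$observed, obs, tolerance = 1e-12)
  expect_equal(sn$values[1], obs, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sn$values[2], obs)))
})

test_that("spin null is seed-reproducible and never returns p = 0", {
  cfg <- sim_config(seed = 14, transcriptome_spec = list(
    n_genes = 4L, samples_per_donor = 30L))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  co <- simulate_cohort(demo_sim_config(seed = 14))
  m <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  s1 <- spatial_null(tx, sph, "GENE_TARGET", m, n_rot = 50L, seed = 9)
  s2 <- spatial_null(tx, sph, "GENE_TARGET", m, n_rot = 50L, seed = 9)
  expect_identical(s1$values, s2$values)
  expect_gt(s1$p_empirical, 0)
})

test_that("a degenerate gene pool gives the maximal p-value", {
  cfg <- sim_config(seed = 20, transcriptome_spec = list(
    n_genes = 12L, samples_per_donor = 30L, probe_offset_sd = 0,
    noise_sd = 0))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  # duplicate the target gene's values into every pool gene
  target_rows <- tx$probes$gene == "GENE_TARGET"
  for (g in tx$genes$gene) {
    tx$values[tx$probes$gene == g, ] <- tx$values[target_rows, ]
  }
  co <- simulate_cohort(demo_sim_config(seed = 20))
  m <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  gn <- gene_null(tx, sph, "GENE_TARGET", m, n_draws = 50L, seed = 1)
  expect_equal(gn$p_empirical, 1)
  expect_true(all(abs(gn$values - gn$observed) < 1e-12))
})

test_that("the brain-gene subset restricts the pool", {
  cfg <- sim_config(seed = 21, transcriptome_spec = list(
    n_genes = 40L, samples_per_donor = 25L, brain_gene_fraction = 0.25))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  co <- simulate_cohort(demo_sim_config(seed = 21))
  m <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  gb <- gene_null(tx, sph, "GENE_TARGET", m, subset = "brain",
                  n_draws = 30L, seed = 2)
  expect_equal(gb$method, "brain_gene")
  expect_error(gene_null(tx, sph, "GENE_TARGET", m, set_size = 50L,
                         n_draws = 10L))
})

test_that("lobe profile is a total partition and finds lobar coupling", {
  lobes <- dk_lobes()
  expect_setequal(names(lobes), dk_regions())
  expect_setequal(unique(unname(lobes)),
                  c("frontal", "parietal", "temporal", "occipital"))
  # expression tracking the map only in temporal regions
  keys <- morphogene:::bilateral_regions()
  set.seed(5)
  d <- stats::setNames(rnorm(68), keys)
  temporal <- keys %in% morphogene:::bilateral_regions(
    names(lobes)[lobes == "temporal"])
  e <- ifelse(temporal, d, rnorm(68) * 2)
  names(e) <- keys
  prof <- lobe_profile(e, d)
  rs <- vapply(prof, `[[`, numeric(1), "r")
  expect_equal(names(which.max(rs)), "temporal")
  expect_gt(rs["temporal"], 0.9)
})
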