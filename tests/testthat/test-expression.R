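test_that("probe collapse takes the arithmetic mean per sample", {
  tx <- toy_expression()
  expect_equal(unname(collapse_probes(tx, "G")), c(4, 2, 5, 7))
  # single-probe gene passes through
  tx1 <- tx
  tx1$probes <- tx1$probes[1, ]
  tx1$values <- tx1$values[1, , drop = FALSE]
  expect_equal(unname(collapse_probes(tx1, "G")), c(5, 1, 2, 6))
  expect_equal(mean(c(1, 2, 6)), 3)
  expect_error(collapse_probes(tx, "NOPE"))
})

test_that("samples on a vertex are assigned to that vertex's parcel", {
  cfg <- sim_config(seed = 1, transcriptome_spec = list(
    n_genes = 3L, samples_per_donor = 25L))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  asg <- assign_samples(tx, sph)
  expect_false(any(is.na(asg$region)))
  # samples sit on vertices; acos of a near-1 dot product is ~1e-6
  expect_true(all(asg$distance < 1e-4))
  lh_labels <- morphogene:::sphere_labels(sph, "lh")
  lh <- tx$samples$hemisphere == "lh"
  expect_identical(asg$region[lh],
                   paste0(lh_labels[tx$samples$vertex_id[lh]], "_lh"))
})

test_that("equidistant samples break ties toward the lowest vertex index", {
  sph <- simulate_sphere_parcellation(sim_config(seed = 1))
  v <- morphogene:::sphere_vertices(sph, "lh")
  # midpoint of vertices 10 and 20, renormalized: equidistant by symmetry
  mid <- (v[10, ] + v[20, ]) / sqrt(sum((v[10, ] + v[20, ])^2))
  tx <- toy_expression()
  tx$samples <- tx$samples[1, ]
  tx$samples[, c("x", "y", "z")] <- as.list(mid)
  tx$values <- tx$values[, 1, drop = FALSE]
  asg <- assign_samples(tx, sph)
  lh_labels <- morphogene:::sphere_labels(sph, "lh")
  d10 <- sum(mid * v[10, ]); d20 <- sum(mid * v[20, ])
  expected <- if (abs(d10 - d20) < 1e-12) lh_labels[10] else
    lh_labels[if (d10 > d20) 10 else 20]
  expect_equal(asg$region, paste0(expected, "_lh"))
})

test_that("non-finite coordinates are excluded, distance threshold applies", {
  sph <- simulate_sphere_parcellation(sim_config(seed = 1))
  tx <- toy_expression()
  tx$samples$x[2] <- NA_real_
  asg <- assign_samples(tx, sph)
  expect_true(is.na(asg$region[2]))
  asg2 <- assign_samples(tx, sph, max_distance = 0)
  expect_true(all(is.na(asg2$region)))
})

test_that("aggregation reproduces hand-computed worked examples", {
  # one donor, one region, samples {2, 4} -> 3
  v <- aggregate_to_regions(c(2, 4), rep("bankssts_lh", 2), rep("d1", 2))
  expect_equal(v$value[v$region == "bankssts" & v$hemisphere == "lh"], 3)
  expect_equal(sum(!is.na(v$value)), 1)
  # donor means {1, 2, 10} -> cross-donor median 2
  v2 <- aggregate_to_regions(c(1, 2, 10), rep("cuneus_rh", 3),
                             c("d1", "d2", "d3"))
  expect_equal(v2$value[v2$region == "cuneus" & v2$hemisphere == "rh"], 2)
  expect_equal(v2$n_donors[v2$region == "cuneus" & v2$hemisphere == "rh"],
               3L)
})

test_that("the chain is invariant to sample order and is idempotent", {
  set.seed(77)
  n <- 120
  expr <- rnorm(n)
  labels <- sample(morphogene:::bilateral_regions(), n, replace = TRUE)
  donors <- sample(paste0("d", 1:4), n, replace = TRUE)
  a <- aggregate_to_regions(expr, labels, donors)
  perm <- sample(n)
  b <- aggregate_to_regions(expr[perm], labels[perm], donors[perm])
  expect_equal(a, b)
  # every sample in a region shares value v => region value v
  const <- aggregate_to_regions(rep(2.5, n), labels, donors)
  expect_true(all(const$value[!is.na(const$value)] == 2.5))
})

test_that("right-hemisphere missingness reflects the donor subset", {
  cfg <- sim_config(seed = 31, transcriptome_spec = list(
    n_genes = 4L, samples_per_donor = 30L, n_right_donors = 2L))
  sph <- simulate_sphere_parcellation(cfg)
  tx <- simulate_transcriptome(cfg, sph)
  expr <- region_expression(tx, sph, tx$genes$gene[1])
  miss_lh <- sum(is.na(expr$value[expr$hemisphere == "lh"]))
  miss_rh <- sum(is.na(expr$value[expr$hemisphere == "rh"]))
  expect_gte(miss_rh, miss_lh)
  n_don_rh <- max(expr$n_donors[expr$hemisphere == "rh"])
  expect_lte(n_don_rh, 2)
})

test_that("median-within-donor switch changes only the stage-1 statistic", {
  expr <- c(1, 2, 9, 5)
  labels <- rep("insula_lh", 4)
  donors <- c("d1", "d1", "d1", "d2")
  a_mean <- aggregate_to_regions(expr, labels, donors, "mean")
  a_med <- aggregate_to_regions(expr, labels, donors, "median")
  key <- a_mean$region == "insula" & a_mean$hemisphere == "lh"
  expect_equal(a_mean$value[key], median(c(4, 5)))
  expect_equal(a_med$value[key], median(c(2, 5)))
})
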