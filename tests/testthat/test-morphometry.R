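make_cohort <- function(seed = 1, em = NULL, ...) {
  simulate_cohort(two_group_config(seed = seed, effect_map = em, ...))
}

test_that("global comparisons recover programmed global deficits", {
  # matched demographics and no covariate slopes, so the realized Welch d
  # estimates the programmed global deficit directly; mean over repeats
  # shrinks the d sampling error (sd ~ 0.25 at n = 30/40) below the band
  ds <- vapply(1:10, function(i) {
    cfg <- sim_config(group_sizes = c(gA = 30L, gB = 40L),
                      global_effects = list(gA = c(tbv = -1.0, tsa = -0.55,
                                                   wmt = -1.04)),
                      covariate_slopes = list(
                        age = c(tbv = 0, tsa = 0, wmt = 0),
                        sex = c(tbv = 0, tsa = 0, wmt = 0)),
                      seed = 4400 + i)
    co <- simulate_cohort(cfg)
    global_comparisons(co, c("gA", "gB"))$tbv$effect_size
  }, numeric(1))
  expect_lt(abs(mean(ds) - (-1.0)), 0.2)
  co <- simulate_cohort(sim_config(seed = 44))
  glob <- global_comparisons(co, c("PTPN11", "TD"))
  expect_named(glob, c("tbv", "tsa", "wmt"))
  expect_error(global_comparisons(co, c("PTPN11", "nope")))
})

test_that("ANCOVA maps carry family-wise FDR and the documented df", {
  co <- make_cohort(seed = 2)
  m <- ancova_map(co, c("PTPN11", "TD"), "gmv")
  expect_equal(nrow(m), 68)
  expect_true(all(m$df1 == 1))
  expect_true(all(m$df2 == 65))  # 70 subjects, 5 parameters
  expect_equal(m$q, bh_stepup_oracle(m$p_raw), tolerance = 1e-12)
  # subcortical family is its own FDR family of 8
  ms <- ancova_map(co, c("PTPN11", "TD"), "vol")
  expect_equal(nrow(ms), 8)
  expect_equal(ms$q, bh_stepup_oracle(ms$p_raw), tolerance = 1e-12)
})

test_that("sensitivity map with the Euler covariate reduces the error df", {
  # euler distribution identical across groups: no confound to absorb
  eq_euler <- list(PTPN11 = c(mean = -160, sd = 60),
                   TD = c(mean = -160, sd = 60))
  co <- make_cohort(seed = 2, euler_spec = eq_euler)
  m <- sensitivity_map(co, c("PTPN11", "TD"), "gmv")
  expect_true(all(m$df2 == 64))  # one extra covariate
  base <- ancova_map(co, c("PTPN11", "TD"), "gmv")
  expect_gt(cor(sqrt(m$statistic), sqrt(base$statistic)), 0.95)
  expect_gt(cor(m$d, base$d), 0.99)
})

test_that("residualized d is invariant to joint rescaling", {
  co <- make_cohort(seed = 5)
  m1 <- effect_size_map(co, c("PTPN11", "TD"), "sa")
  co2 <- co
  cols <- grep("_sa$", names(co2), value = TRUE)
  co2[cols] <- co2[cols] * 2
  co2$tsa_mm2 <- co2$tsa_mm2 * 2
  m2 <- effect_size_map(co2, c("PTPN11", "TD"), "sa")
  expect_equal(m1$d, m2$d, tolerance = 1e-10)
})

test_that("a contrast of a group against itself gives d of zero", {
  co <- make_cohort(seed = 5)
  co2 <- co[co$group == "TD", ]
  half <- seq_len(nrow(co2)) <= nrow(co2) / 2
  co2$group <- ifelse(half, "TD_a", "TD_b")
  co_dup <- rbind(co2, co2)
  co_dup$group <- c(rep("TD_a", nrow(co2)), rep("TD_b", nrow(co2)))
  class(co_dup) <- class(co)
  m <- effect_size_map(co_dup, c("TD_a", "TD_b"), "gmv")
  expect_equal(m$d, rep(0, 68), tolerance = 1e-10)
})

test_that("residual-t and ANCOVA routes agree on large balanced cohorts", {
  em <- cortical_effect_frame(seq(-0.8, 0.8, length.out = 68), "gmv")
  co <- make_cohort(seed = 7, em = em, n1 = 250L, n2 = 250L)
  ma <- ancova_map(co, c("PTPN11", "TD"), "gmv")
  mt <- residual_t_map(co, c("PTPN11", "TD"), "gmv")
  expect_gt(cor(abs(ma$d), abs(mt$d), method = "spearman"), 0.9)
  # p distributions nearly coincide under large balanced designs
  ks <- suppressWarnings(ks.test(ma$p_raw, mt$p_raw)$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("degenerate regions are flagged as missing, never dropped", {
  co <- make_cohort(seed = 9)
  co$bankssts_lh_gmv <- 5000  # zero variance after any adjustment
  expect_warning(m <- ancova_map(co, c("PTPN11", "TD"), "gmv"),
                 "degenerate")
  expect_equal(nrow(m), 68)
  expect_true(is.na(m$p_raw[m$region == "bankssts" &
                              m$hemisphere == "lh"]))
})

test_that("small-subgroup route recovers a wide but centered pallidum d", {
  em <- data.frame(region = "pallidum", hemisphere = c("lh", "rh"),
                   measure = "vol", d = -0.9)
  cfg <- sim_config(group_sizes = c(SOS1 = 10L, TD = 40L),
                    effect_map = em, global_effects = list(), seed = 10)
  co <- simulate_cohort(cfg)
  m <- residual_t_map(co, c("SOS1", "TD"), "vol")
  pall <- m$d[m$region == "pallidum"]
  expect_true(all(abs(pall - (-0.9)) <= 0.6))
})
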