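# Independent brute-force Benjamini-Hochberg step-up: for the sorted raw
# p-values, adj_(i) = min over k >= i of min(1, n * p_(k) / k), mapped back
# to the input order. Deliberately naive (nested loop) so it shares no code
# path with the implementation under test.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (k in i:n) best <- min(best, n * sorted[k] / k)
    adj_sorted[i] <- min(1, best)
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# Effect-map data.frame covering all 68 cortical regions for one measure.
cortical_effect_frame <- function(d, measure = "gmv", group = NULL) {
  out <- data.frame(region = rep(dk_regions(), 2),
                    hemisphere = rep(c("lh", "rh"), each = 34),
                    measure = measure, d = d, stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group
  out
}

# Two-group configuration (patients vs controls) used by recovery tests.
two_group_config <- function(seed, effect_map = NULL, n1 = 30L, n2 = 40L,
                             global_effects = list(), ...) {
  sim_config(group_sizes = c(PTPN11 = n1, TD = n2),
             effect_map = effect_map, global_effects = global_effects,
             seed = seed, ...)
}

# Hand-built minimal expression dataset (two donors, explicit values) for
# worked-example tests of the aggregation chain.
toy_expression <- function() {
  samples <- data.frame(
    donor_id = c("d1", "d1", "d2", "d2"),
    sample_id = c("s1", "s2", "s3", "s4"),
    x = c(0, 0, 0, 0), y = c(1, 1, 1, 1), z = c(0, 0, 0, 0),
    hemisphere = "lh", vertex_id = NA_integer_,
    stringsAsFactors = FALSE)
  values <- matrix(c(5, 1, 2, 6,
                     3, 3, 8, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("p1", "p2"),
                                   c("s1", "s2", "s3", "s4")))
  structure(
    list(samples = samples, values = values,
         probes = data.frame(probe_id = c("p1", "p2"), gene = "G",
                             stringsAsFactors = FALSE),
         genes = data.frame(gene = "G", is_brain = TRUE, is_target = TRUE,
                            stringsAsFactors = FALSE),
         latent = NULL),
    class = "expression_dataset")
}
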