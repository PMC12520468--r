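test_that("config invariants are enforced with named messages", {
  expect_error(simulation_config(n_genes = 10, module_size = 10),
               "module_size")
  expect_error(simulation_config(n_replicates = 2), "n_replicates")
  expect_error(simulation_config(t_star = 5, n_timepoints = 5), "t_star")
  expect_error(simulation_config(factor_sd_base = 1, factor_sd_peak = 0.5),
               "factor_sd")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
})

test_that("simulation is deterministic given seed and all values finite", {
  cfg <- simulation_config(n_genes = 50, module_size = 8, n_neighbors = 10,
                           seed = 99)
  a <- simulate_critical_transition(cfg)
  b <- simulate_critical_transition(cfg)
  expect_identical(a$series$values, b$series$values)
  expect_identical(a$truth$module_genes, b$truth$module_genes)
  expect_true(all(is.finite(a$series$values)))
  expect_true(length(intersect(a$truth$module_genes,
                               a$truth$neighbor_genes)) == 0)
})

test_that("no-effect configuration records no shifted genes", {
  cfg <- simulation_config(n_genes = 40, module_size = 6, n_neighbors = 5,
                           factor_sd_peak = 0.2, background_coupling = 0,
                           mean_shift = 0, seed = 1)
  sim <- simulate_critical_transition(cfg)
  expect_length(sim$truth$shifted_genes, 0)
})

test_that("within-module correlation matches the one-factor closed form", {
  # lambda = 1, s1 = 2, sigma_e = 0.5: population r = 4 / (4 + 0.25) = 0.9412
  cfg <- simulation_config(n_genes = 40, module_size = 20, n_neighbors = 5,
                           n_timepoints = 2, t_star = 1, n_replicates = 500,
                           loading_range = c(1, 1), factor_sd_base = 0.2,
                           factor_sd_peak = 2, noise_sd = 0.5,
                           background_coupling = 0, seed = 7)
  sim <- simulate_critical_transition(cfg)
  tp <- sim$truth$tipping_label
  x <- sim$series$values[sim$truth$module_genes,
                         grepl(paste0("^", tp, "_"),
                               colnames(sim$series$values))]
  rr <- abs(cor(t(x)))
  mean_r <- mean(rr[upper.tri(rr)])
  expect_equal(mean_r, 4 / 4.25, tolerance = 0.01)
})

test_that("module SD peaks at the transition and coupling drops after it", {
  sd_gap <- cor_pre <- cor_post <- numeric(0)
  for (s in 1:200) {
    cfg <- simulation_config(n_genes = 20, module_size = 5, n_neighbors = 3,
                             n_timepoints = 3, t_star = 1,
                             factor_sd_base = 0.5,
                             background_coupling = 0.8, seed = s)
    sim <- simulate_critical_transition(cfg)
    per_tp_sd <- vapply(sim$series$timepoints, function(tp) {
      x <- sim$series$values[sim$truth$module_genes,
                             grepl(paste0("^", tp, "_"),
                                   colnames(sim$series$values))]
      mean(apply(x, 1, sd))
    }, 0)
    sd_gap <- c(sd_gap, per_tp_sd[2] - max(per_tp_sd[-2]))
    bg <- setdiff(sim$series$gene_ids, sim$truth$module_genes)
    xm <- sim$series$values[sim$truth$module_genes, , drop = FALSE]
    xb <- sim$series$values[bg, , drop = FALSE]
    pre <- grepl("^T1_", colnames(xm))
    post <- grepl("^T3_", colnames(xm))
    cor_pre <- c(cor_pre,
                 mean(abs(cor(t(xm[, pre]), t(xb[, pre])))))
    cor_post <- c(cor_post,
                  mean(abs(cor(t(xm[, post]), t(xb[, post])))))
  }
  # the invariant is about the expectation; the per-seed gap is noisy with
  # 3 replicates and a 0.5-SD baseline factor
  expect_gt(mean(sd_gap) / (sd(sd_gap) / sqrt(length(sd_gap))), 5)
  expect_gt(mean(sd_gap > 0), 0.75)
  # coupling 0.3 on an s0 = 0.2 factor is a weak pre-transition signal, so
  # compare the Monte-Carlo means, not per-seed
  expect_gt(mean(cor_pre), mean(cor_post))
})

test_that("planted PPI graph has exact degenerate edge sets", {
  cfg <- simulation_config(n_genes = 200, module_size = 10, n_neighbors = 5,
                           seed = 3)
  truth <- simulate_critical_transition(cfg)$truth

  g0 <- simulate_ppi(truth, n_extra_nodes = 20, p_background_edge = 0,
                     seed = 1)
  expect_equal(igraph::ecount(g0), 10 * 5)
  el <- igraph::as_data_frame(g0)
  in_mod <- function(v) v %in% truth$module_genes
  expect_true(all(xor(in_mod(el$from), in_mod(el$to))))

  g1 <- simulate_ppi(truth, n_extra_nodes = 10, p_background_edge = 1,
                     seed = 1)
  n <- igraph::vcount(g1)
  expect_equal(igraph::ecount(g1), n * (n - 1) / 2)
})

test_that("background edge count falls in the binomial 99% interval", {
  cfg <- simulation_config(n_genes = 200, module_size = 10, n_neighbors = 5,
                           seed = 3)
  truth <- simulate_critical_transition(cfg)$truth
  p <- 0.1
  g <- simulate_ppi(truth, n_extra_nodes = 100, p_background_edge = p,
                    seed = 11)
  n_nodes <- 10 + 5 + 100
  n_candidate <- n_nodes * (n_nodes - 1) / 2 - 10 * 5   # direct enumeration
  n_bg <- igraph::ecount(g) - 10 * 5
  bounds <- qbinom(c(0.005, 0.995), n_candidate, p)
  expect_gte(n_bg, bounds[1])
  expect_lte(n_bg, bounds[2])
})
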