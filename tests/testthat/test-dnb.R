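test_that("module statistics match hand computation on tiny cases", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(9, 9, 9))
  rownames(m) <- c("gA", "gB", "gC")
  es <- make_series(m, n_rep = 3)
  expect_warning(st <- module_stats(es, c("gA", "gB"), "T1"),
                 "zero replicate variance")
  expect_equal(st$pcc_in, 1.0)
  expect_equal(st$sd_in, (1 + 2) / 2)
  expect_equal(st$pcc_out, 0)        # only gC outside, zero variance

  # both module genes constant -> pcc_in 0
  m2 <- rbind(c(5, 5, 5), c(7, 7, 7), c(1, 2, 4))
  rownames(m2) <- c("gA", "gB", "gC")
  es2 <- make_series(m2, n_rep = 3)
  expect_warning(st2 <- module_stats(es2, c("gA", "gB"), "T1"))
  expect_equal(st2$pcc_in, 0)

  expect_error(module_stats(es, "gA", "T1"), class = "dnbtip_bad_module")
  es_2rep <- make_series(matrix(rnorm(8), 2, 4,
                                dimnames = list(c("gA", "gB"), NULL)),
                         n_rep = 2)
  expect_error(module_stats(es_2rep, c("gA", "gB"), "T1"),
               class = "dnbtip_too_few_replicates")
})

test_that("module statistics equal exhaustive pair loops", {
  set.seed(41)
  for (i in 1:30) {
    ng <- sample(4:12, 1)
    m <- matrix(rnorm(ng * 3), ng, 3)
    rownames(m) <- sprintf("g%02d", seq_len(ng))
    es <- make_series(m, n_rep = 3)
    mod <- sort(sample(rownames(m), sample(2:(ng - 1), 1)))
    got <- module_stats(es, mod, "T1")
    want <- oracle_module_stats(m, match(mod, rownames(m)))
    expect_equal(got$sd_in, want$sd_in, tolerance = 1e-12)
    expect_equal(got$pcc_in, want$pcc_in, tolerance = 1e-12)
    expect_equal(got$pcc_out, want$pcc_out, tolerance = 1e-12)
  }
})

test_that("criticality index arithmetic and monotonicity", {
  st <- list(size = 2, pcc_in = 0.5, sd_in = 2.0, pcc_out = 0.25)
  expect_equal(criticality_index(st, epsilon = 1e-12), 8.0,
               tolerance = 1e-9)
  expect_equal(criticality_index(st, use_size_weight = FALSE,
                                 epsilon = 1e-12), 4.0, tolerance = 1e-9)
  st$pcc_in <- 0
  expect_equal(criticality_index(st), 0)
  expect_error(criticality_index(st, epsilon = 0),
               class = "dnbtip_bad_config")

  set.seed(42)
  for (i in 1:50) {
    base <- list(size = sample(2:50, 1), pcc_in = runif(1, 0.05, 0.95),
                 sd_in = runif(1, 0.1, 3), pcc_out = runif(1, 0.05, 0.95))
    ci0 <- criticality_index(base)
    up <- base; up$sd_in <- up$sd_in + runif(1, 0.01, 1)
    expect_gt(criticality_index(up), ci0)
    up <- base; up$pcc_in <- min(1, up$pcc_in + runif(1, 0.01, 0.04))
    expect_gt(criticality_index(up), ci0)
    dn <- base; dn$pcc_out <- dn$pcc_out + runif(1, 0.01, 0.04)
    expect_lt(criticality_index(dn), ci0)
  }
})

test_that("planted perfectly correlated blocks appear among candidates", {
  set.seed(43)
  base1 <- rnorm(12); base2 <- rnorm(12)
  block1 <- t(vapply(1:6, function(i) 2 + i * base1, numeric(12)))
  block2 <- t(vapply(1:6, function(i) 5 - i * base2, numeric(12)))
  noise <- matrix(rnorm(20 * 12), 20, 12)
  m <- rbind(block1, block2, noise)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  es <- make_series(m, n_rep = 3)
  cands <- candidate_modules(es, min_size = 5, cut_heights = 0.5)
  keys <- vapply(cands, paste, "", collapse = ",")
  expect_true(paste(sprintf("g%02d", 1:6), collapse = ",") %in% keys)
  expect_true(paste(sprintf("g%02d", 7:12), collapse = ",") %in% keys)
})

test_that("candidate search is order-invariant and honours size window", {
  set.seed(44)
  m <- matrix(rnorm(30 * 9), 30, 9)
  rownames(m) <- sprintf("g%02d", 1:30)
  es <- make_series(m, n_rep = 3)
  expect_identical(candidate_modules(es, min_size = 40), list())
  c1 <- candidate_modules(es, min_size = 3, linkage = "average")
  perm <- sample(30)
  es_p <- make_series(m[perm, ], n_rep = 3)
  c2 <- candidate_modules(es_p, min_size = 3, linkage = "average")
  norm <- function(x) sort(vapply(x, paste, "", collapse = ","))
  expect_identical(norm(c1), norm(c2))
})

test_that("planted transition is detected at the planted timepoint", {
  sim <- simulate_critical_transition(simulation_config(seed = 1))
  fit <- dnb_detect(sim$series)
  expect_s3_class(fit, "dnb")
  expect_identical(fit$tipping_timepoint, sim$truth$tipping_label)
  expect_gt(jaccard(fit$module_genes, sim$truth$module_genes), 0.5)
  expect_equal(fit$ci_peak, max(fit$stats$ci))
  expect_named(fit$criteria, c("sd_in_increased", "pcc_in_increased",
                               "pcc_out_decreased"))
  # determinism
  fit2 <- dnb_detect(sim$series)
  expect_identical(fit$module_genes, fit2$module_genes)
  expect_identical(fit$stats, fit2$stats)
})

test_that("a supplied module reproduces hand-computed profile and flags", {
  set.seed(45)
  m <- matrix(rnorm(8 * 9), 8, 9)
  rownames(m) <- sprintf("g%d", 1:8)
  es <- make_series(m, n_rep = 3)
  mod <- c("g2", "g5", "g7")
  fit <- dnb_detect(es, module_genes = mod)
  for (j in 1:3) {
    st <- module_stats(es, mod, es$timepoints[j])
    expect_equal(fit$stats$sd_in[j], st$sd_in, tolerance = 1e-12)
    expect_equal(fit$stats$pcc_in[j], st$pcc_in, tolerance = 1e-12)
    expect_equal(fit$stats$pcc_out[j], st$pcc_out, tolerance = 1e-12)
    expect_equal(fit$stats$ci[j], criticality_index(st), tolerance = 1e-12)
  }
  i <- which.max(fit$stats$ci)
  expect_identical(fit$tipping_timepoint, fit$stats$timepoint[i])
  expect_identical(unname(fit$criteria["sd_in_increased"]),
                   fit$stats$sd_in[i] > max(fit$stats$sd_in[-i]) +
                     sd(fit$stats$sd_in[-i]))
})

test_that("permutation p hits its extreme-case values", {
  sim <- simulate_critical_transition(
    simulation_config(n_genes = 60, module_size = 8, n_neighbors = 5,
                      seed = 46))
  tp <- sim$truth$tipping_label
  lo <- permutation_null(sim$series, 8, tp, B = 50, seed = 2,
                         observed_ci = -1)
  expect_equal(lo$p, 1)
  hi <- permutation_null(sim$series, 8, tp, B = 50, seed = 2,
                         observed_ci = max(lo$null_ci) + 1)
  expect_equal(hi$p, 1 / 51)
  again <- permutation_null(sim$series, 8, tp, B = 50, seed = 2,
                            observed_ci = -1)
  expect_identical(lo$null_ci, again$null_ci)
})

test_that("dnb methods print, summarise, plot and expose coefficients", {
  sim <- simulate_critical_transition(
    simulation_config(n_genes = 50, module_size = 8, n_neighbors = 5,
                      seed = 47))
  fit <- dnb_detect(sim$series, min_size = 3)
  expect_output(print(fit), "tipping point")
  expect_output(summary(fit), "per-timepoint statistics")
  expect_named(coef(fit), sim$series$timepoints)
  f <- tempfile(fileext = ".pdf")
  pdf(f); plot(fit); dev.off()
  expect_true(file.exists(f))
})
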