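test_that("first neighbors of seeds on hand-built and random graphs", {
  g <- ppi_graph(c("A", "B"), c("B", "C"))
  expect_identical(neighbor_genes(g, "B"), c("A", "C"))
  expect_identical(neighbor_genes(g, "Z"), character(0))
  g_iso <- ppi_graph("A", "B", nodes = c("A", "B", "C"))
  expect_identical(neighbor_genes(g_iso, "C"), character(0))

  set.seed(51)
  for (i in 1:10) {
    n <- 15
    nodes <- sprintf("n%02d", 1:n)
    adj <- matrix(runif(n * n) < 0.2, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    g <- ppi_graph(nodes[idx[, 1]], nodes[idx[, 2]], nodes = nodes)
    seeds <- sample(nodes, 3)
    # brute-force adjacency scan
    sym <- adj | t(adj)
    want <- sort(setdiff(
      nodes[rowSums(sym[, match(seeds, nodes), drop = FALSE]) > 0], seeds))
    expect_identical(neighbor_genes(g, seeds), want)
  }
})

test_that("set intersections equal naive set algebra", {
  expect_identical(
    dnb_neighbor_degs(c("a", "b"), list(C1 = "x", C2 = "y"), c("C1", "C2")),
    character(0))
  expect_identical(
    dnb_neighbor_degs(c("a", "b"), list(C1 = c("a", "b", "z")), "C1"),
    c("a", "b"))
  expect_error(
    dnb_neighbor_degs("a", list(C1 = "a"), "C9"),
    class = "dnbtip_unknown_contrast")
  expect_identical(metastasis_filter(c("a", "b"), list(M = "q")),
                   character(0))

  set.seed(52)
  pool <- sprintf("g%03d", 1:100)
  for (i in 1:20) {
    nbrs <- sample(pool, 30)
    degs <- list(A = sample(pool, 40), B = sample(pool, 40))
    mets <- list(M1 = sample(pool, 25), M2 = sample(pool, 25))
    got <- dnb_neighbor_degs(nbrs, degs, c("A", "B"))
    want <- sort(nbrs[nbrs %in% c(degs$A, degs$B)])
    expect_identical(got, want)
    got2 <- metastasis_filter(nbrs, mets)
    expect_identical(got2, sort(nbrs[nbrs %in% c(mets$M1, mets$M2)]))
  }
})

test_that("gene-set correlation edges match the formula oracle", {
  set.seed(53)
  m <- matrix(rnorm(12 * 12), 12, 12)
  rownames(m) <- sprintf("g%02d", 1:12)
  es <- make_series(m, n_rep = 3)
  res <- correlate_gene_sets(es, rownames(m)[1:6], rownames(m)[7:12],
                             r_threshold = 0.3, p_threshold = 0.2)
  for (k in seq_len(nrow(res$edges))) {
    e <- res$edges[k, ]
    want <- oracle_cor_p(m[e$gene_a, ], m[e$gene_b, ])
    expect_equal(e$r, want$r, tolerance = 1e-12)
    expect_equal(e$p, want$p, tolerance = 1e-12)
    expect_identical(e$passes, abs(want$r) > 0.3 && want$p < 0.2)
  }
  expect_false(is.unsorted(-res$counts))
})

test_that("duplicated expression passes and exact-threshold r fails", {
  x <- c(0, 1, 2, 3, 1.5, 2.5, 0.5, 3.5, 2, 1)
  u <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  w <- residuals(lm(rnorm(10) ~ x))
  w <- w / sqrt(sum(w^2))
  y8 <- 0.8 * u + sqrt(1 - 0.64) * w      # exact r = 0.8 by construction
  m <- rbind(A = x, Adup = x, B = y8, C = rnorm(10))
  es <- make_series(m, n_rep = 5, tp_labels = c("T1", "T2"))
  res <- correlate_gene_sets(es, "A", c("Adup", "B", "C"))
  dup <- res$edges[res$edges$gene_b == "Adup", ]
  expect_equal(dup$r, 1)
  expect_true(dup$passes)
  edge8 <- res$edges[res$edges$gene_b == "B", ]
  expect_equal(edge8$r, 0.8, tolerance = 1e-12)
  # strict inequality at the threshold: |r| equal to the cutoff fails
  res_exact <- correlate_gene_sets(es, "A", "B",
                                   r_threshold = abs(edge8$r))
  expect_false(res_exact$edges$passes)

  # zero-variance partner is reported, not propagated as NaN
  m2 <- rbind(A = x, Z = rep(1, 10))
  es2 <- make_series(m2, n_rep = 5, tp_labels = c("T1", "T2"))
  expect_warning(res2 <- correlate_gene_sets(es2, "A", "Z"),
                 "zero-variance")
  expect_equal(res2$edges$r, 0)
  expect_equal(res2$edges$p, 1)
})

test_that("pathway activity is the mean member z-score", {
  set.seed(54)
  m <- matrix(rnorm(6 * 8), 6, 8)
  rownames(m) <- sprintf("g%d", 1:6)
  es <- make_series(m, n_rep = 2)
  sets <- list(good = c("g1", "g2", "g3"), tiny = "g4",
               twin = c("g5", "g5x"))
  expect_warning(pa <- pathway_activity(es, sets[c("good", "tiny")]),
                 "< 2 members")
  expect_false("tiny" %in% rownames(pa$scores))
  z <- t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(unname(pa$scores["good", ]),
               unname(colMeans(z[c("g1", "g2", "g3"), ])),
               tolerance = 1e-12)

  # two identical member genes: pathway score equals either gene's z
  m2 <- rbind(m, g5x = m["g5", ])
  es2 <- make_series(m2, n_rep = 2)
  pa2 <- pathway_activity(es2, sets["twin"])
  z5 <- (m["g5", ] - mean(m["g5", ])) / sd(m["g5", ])
  expect_equal(unname(pa2$scores["twin", ]), unname(z5), tolerance = 1e-12)
})

test_that("gene-pathway association applies the 0.5 strict threshold", {
  set.seed(55)
  m <- matrix(rnorm(8 * 12), 8, 12)
  rownames(m) <- sprintf("g%d", 1:8)
  es <- make_series(m, n_rep = 3)
  pa <- pathway_activity(es, list(P1 = c("g5", "g6"), P2 = c("g7", "g8")))
  assoc <- correlate_dnb_pathways(es, c("g1", "g2"), pa)
  for (k in seq_len(nrow(assoc))) {
    want <- oracle_cor_p(m[assoc$gene[k], ], pa$scores[assoc$pathway[k], ])
    expect_equal(assoc$r[k], want$r, tolerance = 1e-12)
    expect_equal(assoc$p[k], want$p, tolerance = 1e-12)
    expect_identical(assoc$passes[k],
                     abs(want$r) > 0.5 && want$p < 0.05)
  }
})

test_that("dysregulation network keeps only passing edges", {
  set.seed(56)
  shared <- rnorm(12)
  m <- rbind(d1 = shared + rnorm(12, sd = 0.1),
             d2 = rnorm(12),
             m1 = shared + rnorm(12, sd = 0.1),
             m2 = rnorm(12))
  es <- make_series(m, n_rep = 3)
  net <- build_dysregulation_network(es, c("d1", "d2"), c("m1", "m2"))
  expect_true(all(net$passes))
  expect_true(all(abs(net$r) > 0.7 & net$p < 0.05))
  expect_true(nrow(net) >= 1)
  expect_true(any(net$gene_a == "d1" & net$gene_b == "m1"))
})
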