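# Independent oracle implementations used to check the package's statistics.
# These deliberately use naive loops / textbook formulas, not the package's
# code paths.

# brute-force module statistics: explicit double loops over gene pairs
oracle_module_stats <- function(x_tp, mod_idx) {
  sds <- apply(x_tp, 1, sd)
  pair_r <- function(i, j) {
    if (sds[i] == 0 || sds[j] == 0) return(0)
    abs(cor(x_tp[i, ], x_tp[j, ]))
  }
  m <- length(mod_idx)
  out_idx <- setdiff(seq_len(nrow(x_tp)), mod_idx)
  rin <- c()
  for (a in seq_len(m - 1)) for (b in (a + 1):m)
    rin <- c(rin, pair_r(mod_idx[a], mod_idx[b]))
  rout <- c()
  for (a in mod_idx) for (b in out_idx) rout <- c(rout, pair_r(a, b))
  list(sd_in = mean(sds[mod_idx]), pcc_in = mean(rin),
       pcc_out = if (length(out_idx)) mean(rout) else 0)
}

# textbook Pearson r and two-sided t-based p
oracle_cor_p <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE))
}

# literal BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# shrunken-variance two-group t, written independently from first principles
oracle_moderated_t <- function(g1, g2, d0, s02) {
  n1 <- ncol(g1); n2 <- ncol(g2)
  d <- n1 + n2 - 2
  out <- t(vapply(seq_len(nrow(g1)), function(i) {
    a <- g1[i, ]; b <- g2[i, ]
    lfc <- mean(a) - mean(b)
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / d
    st <- (d0 * s02 + d * s2) / (d0 + d)
    tt <- lfc / sqrt(st * (1 / n1 + 1 / n2))
    c(lfc, tt, 2 * pt(abs(tt), df = d0 + d, lower.tail = FALSE))
  }, numeric(3)))
  list(lfc = out[, 1], t = out[, 2], p = out[, 3])
}

# build a small expression_series from a genes x (timepoints*reps) matrix
make_series <- function(values, n_rep, tp_labels = NULL) {
  n_tp <- ncol(values) / n_rep
  if (is.null(tp_labels)) tp_labels <- paste0("T", seq_len(n_tp))
  cn <- as.vector(vapply(tp_labels, function(tp)
    sprintf("%s_R%d", tp, seq_len(n_rep)), character(n_rep)))
  colnames(values) <- cn
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  si <- data.frame(sample = cn,
                   timepoint = rep(tp_labels, each = n_rep),
                   replicate = rep(seq_len(n_rep), n_tp),
                   stringsAsFactors = FALSE)
  expression_series(values, si)
}

# adjusted Rand index (contingency-table formula)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# four distinct temporal patterns with additive noise, for clustering tests
make_patterns <- function(n_per = 30, noise = 0.1, n_tp = 5) {
  shapes <- rbind(seq(-1, 1, length.out = n_tp),        # rising
                  seq(1, -1, length.out = n_tp),        # falling
                  c(-1, 0.5, 1, 0.5, -1)[seq_len(n_tp)],  # peak
                  c(1, -0.5, -1, -0.5, 1)[seq_len(n_tp)]) # valley
  prof <- shapes[rep(1:4, each = n_per), ] +
    matrix(rnorm(4 * n_per * n_tp, sd = noise), 4 * n_per, n_tp)
  rownames(prof) <- sprintf("g%03d", seq_len(nrow(prof)))
  list(profiles = prof, labels = rep(1:4, each = n_per))
}
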