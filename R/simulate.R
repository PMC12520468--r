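# One-factor simulator with a planted critical transition. The DNB criteria
# constrain only second moments (within-module SD and correlation rise at the
# tipping point, module-background correlation falls), so a single latent
# factor whose SD jumps at the transition timepoint reproduces exactly that
# signature and keeps the expected SD_in/PCC_in/PCC_out available in closed
# form for oracle tests.

#' Configuration for the planted-transition simulator
#'
#' The latent factor z is drawn once per (timepoint, replicate) with SD
#' `factor_sd_base` (s0) everywhere except the transition timepoint `t_star`,
#' where its SD is `factor_sd_peak` (s1). Module genes load on the factor
#' with per-gene loadings drawn from `loading_range`; background genes load
#' with `background_coupling` before `t_star` and 0 from `t_star` on.
#' Replicates are the correlation sample space, matching an n-of-3 replicate
#' design. An optional persistent `mean_shift` is added to module and
#' planted-neighbor genes from `t_star` on, giving differential-expression
#' calls a planted truth as well.
#'
#' @param n_genes total number of genes.
#' @param module_size number of genes in the planted module.
#' @param n_timepoints number of ordered timepoints (labelled T1, T2, ...).
#' @param n_replicates replicates per timepoint (>= 3).
#' @param t_star 0-based index of the transition timepoint.
#' @param factor_sd_base baseline latent-factor SD s0 (log-expression units).
#' @param factor_sd_peak factor SD s1 at `t_star` (s1 >= s0).
#' @param loading_range interval for per-gene module loadings.
#' @param noise_sd residual SD (> 0).
#' @param background_coupling pre-transition factor loading of background
#'   genes; drops to 0 at `t_star`.
#' @param baseline_mean_range interval for per-gene baseline means.
#' @param mean_shift additive expression shift applied to module and
#'   planted-neighbor genes for timepoints >= `t_star` (0 = no shift).
#' @param n_neighbors number of background genes designated as planted PPI
#'   neighbors of the module.
#' @param seed integer RNG seed; all sub-streams are derived from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200, module_size = 20,
                              n_timepoints = 5, n_replicates = 3,
                              t_star = 2, factor_sd_base = 0.2,
                              factor_sd_peak = 2.0,
                              loading_range = c(0.8, 1.2),
                              noise_sd = 0.5, background_coupling = 0.3,
                              baseline_mean_range = c(4, 8),
                              mean_shift = 0, n_neighbors = 30, seed = 1) {
  cfg <- list(n_genes = n_genes, module_size = module_size,
              n_timepoints = n_timepoints, n_replicates = n_replicates,
              t_star = t_star, factor_sd_base = factor_sd_base,
              factor_sd_peak = factor_sd_peak, loading_range = loading_range,
              noise_sd = noise_sd, background_coupling = background_coupling,
              baseline_mean_range = baseline_mean_range,
              mean_shift = mean_shift, n_neighbors = n_neighbors, seed = seed)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$module_size >= cfg$n_genes)
    dnb_stop("bad_config", "module_size must be < n_genes")
  if (cfg$n_replicates < 3)
    dnb_stop("bad_config", "n_replicates must be >= 3")
  if (cfg$t_star < 0 || cfg$t_star >= cfg$n_timepoints)
    dnb_stop("bad_config", "t_star must satisfy 0 <= t_star < n_timepoints")
  if (cfg$factor_sd_base < 0 || cfg$factor_sd_peak < cfg$factor_sd_base)
    dnb_stop("bad_config",
             "factor_sd_peak >= factor_sd_base >= 0 is required")
  if (cfg$noise_sd <= 0)
    dnb_stop("bad_config", "noise_sd must be > 0")
  if (cfg$n_neighbors > cfg$n_genes - cfg$module_size)
    dnb_stop("bad_config",
             "n_neighbors must fit among non-module genes")
  invisible(cfg)
}

# run expr with a derived, restorable RNG stream; offsets keep derived seeds
# within 32-bit integer range
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Simulate replicated time-series expression with a planted transition
#'
#' @param config a [simulation_config].
#' @return list with `series` (an [expression_series]) and `truth` (a
#'   `simulation_truth`: `module_genes`, `neighbor_genes`, `shifted_genes`,
#'   `t_star`, the timepoint label `tipping_label`, and the config).
#' @examples
#' sim <- simulate_critical_transition(simulation_config(seed = 7))
#' sim$series
#' sim$truth$t_star
#' @export
simulate_critical_transition <- function(config) {
  validate_simulation_config(config)
  g <- config$n_genes; m <- config$module_size
  tps <- paste0("T", seq_len(config$n_timepoints))
  nrep <- config$n_replicates
  genes <- sprintf("G%04d", seq_len(g))

  module <- with_seed(config$seed + 11L,
                      sort(sample(genes, m)))
  background <- setdiff(genes, module)
  neighbors <- with_seed(config$seed + 12L,
                         sort(sample(background, config$n_neighbors)))
  mu <- with_seed(config$seed + 13L,
                  stats::runif(g, config$baseline_mean_range[1],
                               config$baseline_mean_range[2]))
  lambda <- with_seed(config$seed + 14L,
                      stats::runif(g, config$loading_range[1],
                                   config$loading_range[2]))
  names(mu) <- names(lambda) <- genes

  s_t <- rep(config$factor_sd_base, config$n_timepoints)
  s_t[config$t_star + 1] <- config$factor_sd_peak
  z <- with_seed(config$seed + 15L, {
    matrix(stats::rnorm(config$n_timepoints * nrep),
           config$n_timepoints, nrep) * s_t
  })
  eps <- with_seed(config$seed + 16L, {
    array(stats::rnorm(g * config$n_timepoints * nrep, sd = config$noise_sd),
          dim = c(g, config$n_timepoints, nrep))
  })

  is_module <- genes %in% module
  load_mat <- matrix(0, g, config$n_timepoints)   # gene x timepoint loading
  for (t in seq_len(config$n_timepoints)) {
    w_bg <- if (t - 1 < config$t_star) config$background_coupling else 0
    load_mat[, t] <- ifelse(is_module, lambda, w_bg)
  }
  shifted <- if (config$mean_shift != 0) sort(c(module, neighbors))
             else character(0)
  vals <- matrix(NA_real_, g, config$n_timepoints * nrep)
  cn <- character(config$n_timepoints * nrep)
  for (t in seq_len(config$n_timepoints)) {
    for (r in seq_len(nrep)) {
      j <- (t - 1) * nrep + r
      x <- mu + load_mat[, t] * z[t, r] + eps[, t, r]
      if (length(shifted) && t - 1 >= config$t_star)
        x[genes %in% shifted] <- x[genes %in% shifted] + config$mean_shift
      vals[, j] <- x
      cn[j] <- sprintf("%s_R%d", tps[t], r)
    }
  }
  dimnames(vals) <- list(genes, cn)
  si <- data.frame(sample = cn,
                   timepoint = rep(tps, each = nrep),
                   replicate = rep(seq_len(nrep), config$n_timepoints),
                   stringsAsFactors = FALSE)
  truth <- structure(list(module_genes = module, neighbor_genes = neighbors,
                          shifted_genes = shifted, t_star = config$t_star,
                          tipping_label = tps[config$t_star + 1],
                          config = config),
                     class = "simulation_truth")
  list(series = expression_series(vals, si), truth = truth)
}

#' Simulate a planted PPI graph around the simulated module
#'
#' Every (module gene, neighbor gene) pair is an edge; among all other node
#' pairs, background edges are added independently with probability
#' `p_background_edge`. Extra nodes are drawn from the simulated background
#' genes that are not planted neighbors.
#'
#' @param truth a `simulation_truth` from [simulate_critical_transition].
#' @param n_extra_nodes number of additional (non-module, non-neighbor)
#'   genes to include as graph nodes.
#' @param p_background_edge probability of each non-planted edge.
#' @param seed RNG seed.
#' @return a `ppi_graph`.
#' @export
simulate_ppi <- function(truth, n_extra_nodes = 100,
                         p_background_edge = 0.01, seed = 1) {
  if (p_background_edge < 0 || p_background_edge > 1)
    dnb_stop("bad_config", "p_background_edge must be in [0, 1]")
  genes <- sprintf("G%04d", seq_len(truth$config$n_genes))
  pool <- setdiff(genes, c(truth$module_genes, truth$neighbor_genes))
  if (n_extra_nodes > length(pool))
    dnb_stop("bad_config", sprintf(
      "n_extra_nodes (%d) exceeds available background genes (%d)",
      n_extra_nodes, length(pool)))
  extra <- with_seed(seed + 21L, sort(sample(pool, n_extra_nodes)))
  nodes <- c(truth$module_genes, truth$neighbor_genes, extra)

  planted <- expand.grid(from = truth$module_genes,
                         to = truth$neighbor_genes,
                         stringsAsFactors = FALSE)
  pairs <- utils::combn(nodes, 2)
  lo <- pmin(pairs[1, ], pairs[2, ]); hi <- pmax(pairs[1, ], pairs[2, ])
  planted_key <- paste(pmin(planted$from, planted$to),
                       pmax(planted$from, planted$to), sep = "\r")
  is_planted <- paste(lo, hi, sep = "\r") %in% planted_key
  keep_bg <- with_seed(seed + 22L,
                       stats::runif(length(lo)) < p_background_edge)
  sel <- is_planted | (!is_planted & keep_bg)
  ppi_graph(lo[sel], hi[sel], nodes = nodes)
}

#' Jaccard index between two gene sets
#' @param a,b character vectors.
#' @return |a intersect b| / |a union b| (1 if both empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: %d-gene module, %d neighbors, transition at %s\n",
    length(x$module_genes), length(x$neighbor_genes), x$tipping_label))
  invisible(x)
}
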