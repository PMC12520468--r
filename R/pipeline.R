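# Configuration-driven end-to-end pipeline: DEG contrasts -> temporal
# clustering -> DNB search with permutation significance -> PPI-neighbor /
# metastasis intersections -> correlation networks and DNB gene ranking,
# with a run log and fully deterministic outputs under a fixed seed.

#' Pipeline configuration
#'
#' Defaults mirror the analysis thresholds the pipeline is built around:
#' DEG calling at |log2FC| > 1 and p < 0.05, DNB-gene/metastasis-neighbor
#' correlation at |r| > 0.8, gene-pathway association at |r| > 0.5, and the
#' dysregulation network at |r| > 0.7 (all with p < 0.05).
#'
#' @param expression,metadata,ppi_edges,metastasis_gmt,pathway_gmt,out_dir
#'   file/directory paths (`pathway_gmt` may be NULL).
#' @param baseline baseline timepoint label (default: first in metadata).
#' @param lfc_threshold,p_threshold,use_adjusted DEG-calling parameters.
#' @param k,fuzzifier,cluster_tol fuzzy c-means parameters.
#' @param min_size,cut_heights,use_size_weight,epsilon,n_permutations DNB
#'   parameters.
#' @param r_neighbor,r_pathway,r_network correlation thresholds for the
#'   three network stages.
#' @param sample_scope correlation sample space (see [correlate_gene_sets]).
#' @param seed integer seed controlling every random substream.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, metadata, ppi_edges, metastasis_gmt,
                            pathway_gmt = NULL, out_dir = "dnb_results",
                            baseline = NULL, lfc_threshold = 1.0,
                            p_threshold = 0.05, use_adjusted = FALSE,
                            k = 4, fuzzifier = 2.0, cluster_tol = 1e-6,
                            min_size = 5, cut_heights = c(0.3, 0.5, 0.7),
                            use_size_weight = TRUE, epsilon = 1e-6,
                            n_permutations = 200,
                            r_neighbor = 0.8, r_pathway = 0.5,
                            r_network = 0.7,
                            sample_scope = "all_samples", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys are [pipeline_config] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0)
    dnb_stop("bad_config", sprintf(
      "unknown config keys: %s", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm,
                paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

validate_pipeline_config <- function(cfg) {
  for (f in c("expression", "metadata", "ppi_edges", "metastasis_gmt")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      dnb_stop("bad_config", sprintf("config path '%s' does not exist: %s",
                                     f, cfg[[f]]))
  }
  if (!is.null(cfg$pathway_gmt) && !file.exists(cfg$pathway_gmt))
    dnb_stop("bad_config", sprintf("config path 'pathway_gmt' missing: %s",
                                   cfg$pathway_gmt))
  for (f in c("r_neighbor", "r_pathway", "r_network"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      dnb_stop("bad_config", sprintf("%s must be in [0, 1]", f))
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1)
    dnb_stop("bad_config", "p_threshold must be in (0, 1]")
  invisible(cfg)
}

#' Run the full DNB pipeline
#'
#' Reads the configured inputs and writes, in order: per-contrast DEG
#' tables, cluster assignments and centroids, the per-timepoint candidate
#' table with CI, the DNB result manifest (gene list, CI profile, criteria
#' flags, permutation p), neighbor/metastasis intersections, the three
#' correlation networks and the metastasis-neighbor ranking of DNB genes,
#' plus a run log. Identical config + seed gives identical outputs. On a
#' stage failure, partial outputs are retained next to a `FAILED` marker
#' naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return the output directory path, invisibly; the parsed result manifest
#'   is attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("dnbtip run log",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("dnbtip"))),
                 sprintf("seed: %d", config$seed),
                 "config:",
                 vapply(names(unclass(config)), function(nm)
                   sprintf("  %s: %s", nm,
                           paste(format(config[[nm]]), collapse = ", ")),
                   ""))
  stage <- "init"
  log_note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  finish_log <- function()
    writeLines(log_lines, file.path(out, "run_log.txt"))

  result <- withCallingHandlers(
    tryCatch({
      stage <- "read_inputs"
      series <- read_expression_tsv(config$expression, config$metadata)
      graph <- read_edge_list(config$ppi_edges)
      met_sets <- read_gmt(config$metastasis_gmt)
      pw_sets <- if (!is.null(config$pathway_gmt))
        read_gmt(config$pathway_gmt) else NULL
      baseline <- if (is.null(config$baseline)) series$timepoints[1]
                  else config$baseline
      log_note("genes: %d, samples: %d, timepoints: %s",
               nrow(series$values), ncol(series$values),
               paste(series$timepoints, collapse = ","))

      stage <- "diffexpr"
      degs <- fit_degs(series, baseline,
                       lfc_threshold = config$lfc_threshold,
                       p_threshold = config$p_threshold,
                       use_adjusted = config$use_adjusted)
      deg_sets <- call_degs(degs, config$lfc_threshold, config$p_threshold,
                            config$use_adjusted)
      for (ct in unique(degs$contrast)) {
        f <- file.path(out, sprintf("deg_%s.tsv", gsub("/", "_vs_", ct)))
        write_deg_tsv(degs[degs$contrast == ct, ], f)
      }
      log_note("DEGs per contrast: %s",
               paste(sprintf("%s=%d", names(deg_sets), lengths(deg_sets)),
                     collapse = ", "))

      stage <- "temporal_clustering"
      prof <- standardize_profiles(series)
      log_note("profiles clustered: %d (excluded zero-variance: %d)",
               nrow(prof), length(attr(prof, "excluded")))
      fc <- fuzzy_cmeans(prof, k = config$k, m = config$fuzzifier,
                         tol = config$cluster_tol, seed = config$seed + 41)
      write_clustering_tsv(fc, file.path(out, "cluster_membership.tsv"),
                           file.path(out, "cluster_centroids.tsv"))

      stage <- "dnb_detection"
      fit <- dnb_detect(series, min_size = config$min_size,
                        cut_heights = config$cut_heights,
                        use_size_weight = config$use_size_weight,
                        epsilon = config$epsilon,
                        n_permutations = config$n_permutations,
                        seed = config$seed + 42)
      utils::write.table(fit$candidates, file.path(out, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fit$stats, file.path(out, "ci_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(fit$module_genes, file.path(out, "dnb_genes.txt"))
      log_note("DNB: %d genes, tipping at %s, CI %.4f, perm p %.4g",
               length(fit$module_genes), fit$tipping_timepoint, fit$ci_peak,
               fit$perm_p)

      stage <- "network_analysis"
      nbrs <- neighbor_genes(graph, fit$module_genes)
      tip_idx <- match(fit$tipping_timepoint, series$timepoints)
      pre_tip <- setdiff(series$timepoints[seq_len(tip_idx)], baseline)
      pre_contrasts <- intersect(sprintf("%s/%s", pre_tip, baseline),
                                 names(deg_sets))
      nbr_degs <- dnb_neighbor_degs(nbrs, deg_sets, pre_contrasts)
      met_specific <- metastasis_filter(nbr_degs, met_sets)
      writeLines(nbrs, file.path(out, "neighbor_genes.txt"))
      writeLines(nbr_degs, file.path(out, "dnb_neighbor_degs.txt"))
      writeLines(met_specific, file.path(out, "metastasis_specific.txt"))
      log_note("neighbors: %d; neighbor DEGs (%s): %d; metastasis-specific: %d",
               length(nbrs), paste(pre_contrasts, collapse = ","),
               length(nbr_degs), length(met_specific))

      ranking <- NULL
      if (length(met_specific) > 0) {
        cg <- correlate_gene_sets(series, fit$module_genes, met_specific,
                                  config$r_neighbor, config$p_threshold,
                                  config$sample_scope)
        write_network_tsv(cg$edges[cg$edges$passes, , drop = FALSE],
                          file.path(out, "correlation_network.tsv"))
        ranking <- data.frame(gene = names(cg$counts),
                              n_metastasis_neighbors = as.integer(cg$counts),
                              stringsAsFactors = FALSE)
        utils::write.table(ranking, file.path(out, "dnb_ranking.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        net <- build_dysregulation_network(series, fit$module_genes,
                                           met_specific, config$r_network,
                                           config$p_threshold,
                                           config$sample_scope)
        write_network_tsv(net, file.path(out, "dysregulation_network.tsv"))
        log_note("ranking: top gene %s (%d partners); dysregulation edges: %d",
                 ranking$gene[1], ranking$n_metastasis_neighbors[1],
                 nrow(net))
      } else log_note("no metastasis-specific neighbor DEGs; ranking skipped")

      if (!is.null(pw_sets)) {
        pa <- pathway_activity(series, pw_sets)
        assoc <- correlate_dnb_pathways(series, fit$module_genes, pa,
                                        config$r_pathway, config$p_threshold)
        utils::write.table(assoc, file.path(out, "pathway_associations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log_note("pathway associations passing: %d", sum(assoc$passes))
      }

      stage <- "manifest"
      manifest <- list(
        seed = config$seed,
        baseline = baseline,
        dnb = list(module_genes = fit$module_genes,
                   tipping_timepoint = fit$tipping_timepoint,
                   ci_peak = fit$ci_peak,
                   criteria = as.list(fit$criteria),
                   perm_p = fit$perm_p),
        n_neighbors = length(nbrs),
        n_neighbor_degs = length(nbr_degs),
        n_metastasis_specific = length(met_specific),
        top_ranked_gene = if (!is.null(ranking)) ranking$gene[1] else NULL)
      jsonlite::write_json(manifest, file.path(out, "dnb_result.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest
    }, error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
                 file.path(out, "FAILED"))
      finish_log()
      dnb_stop("pipeline_failure", sprintf(
        "pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    }),
    warning = function(w) {
      log_note("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  finish_log()
  invisible(structure(out, manifest = result))
}

#' Write a simulated demo dataset to disk
#'
#' Generates the planted-transition dataset and its PPI graph and writes all
#' pipeline inputs: expression + metadata TSVs, PPI edge list, a synthetic
#' metastasis gene set (planted neighbors plus decoys) and synthetic pathway
#' sets, together with a ground-truth manifest.
#'
#' @param dir output directory.
#' @param config a [simulation_config] (defaults to the reference
#'   simulation with a mean shift of 2 at the transition).
#' @param n_decoys background genes added to the synthetic metastasis set.
#' @param p_background_edge background edge probability for the PPI graph.
#' @return named character vector of paths, invisibly; truth attached as
#'   attribute `"truth"`.
#' @export
make_demo <- function(dir, config = simulation_config(mean_shift = 2),
                      n_decoys = 40, p_background_edge = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_critical_transition(config)
  graph <- simulate_ppi(sim$truth,
                        n_extra_nodes = min(
                          100, config$n_genes - config$module_size -
                            config$n_neighbors),
                        p_background_edge = p_background_edge,
                        seed = config$seed)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             ppi_edges = file.path(dir, "ppi_edges.tsv"),
             metastasis_gmt = file.path(dir, "metastasis.gmt"),
             pathway_gmt = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(sim$series, paths["expression"], paths["metadata"])

  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.table(data.frame(protein1 = el$from, protein2 = el$to),
                     paths["ppi_edges"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pool <- setdiff(sim$series$gene_ids,
                  c(sim$truth$module_genes, sim$truth$neighbor_genes))
  decoys <- with_seed(config$seed + 51,
                      sort(sample(pool, min(n_decoys, length(pool)))))
  met <- list(SYNTHETIC_METASTASIS = sort(c(sim$truth$neighbor_genes,
                                            decoys)))
  attr(met, "descriptions") <- c(SYNTHETIC_METASTASIS =
    "synthetic metastasis-associated set: planted neighbors + decoys")
  class(met) <- "gene_sets"
  write_gmt(met, paths["metastasis_gmt"])

  pw <- with_seed(config$seed + 52, {
    list(SYNTHETIC_MODULE_PATHWAY = sort(sample(sim$truth$module_genes,
           max(2, length(sim$truth$module_genes) %/% 2))),
         SYNTHETIC_RANDOM_PATHWAY_1 = sort(sample(pool, 15)),
         SYNTHETIC_RANDOM_PATHWAY_2 = sort(sample(pool, 15)))
  })
  class(pw) <- "gene_sets"
  write_gmt(pw, paths["pathway_gmt"])

  jsonlite::write_json(
    list(module_genes = sim$truth$module_genes,
         neighbor_genes = sim$truth$neighbor_genes,
         shifted_genes = sim$truth$shifted_genes,
         t_star = sim$truth$t_star,
         tipping_label = sim$truth$tipping_label,
         config = unclass(config)),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(paths, truth = sim$truth))
}
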