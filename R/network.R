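# Correlation-network analysis around a detected DNB module: PPI first
# neighbors, intersection with DEG sets and metastasis gene sets,
# significance-filtered correlation networks at strict |r| thresholds, a
# simple per-sample pathway activity score, and the metastasis-neighbor
# ranking of DNB genes.

#' First neighbors of seed genes in a PPI graph
#'
#' @param graph a `ppi_graph` (see [ppi_graph], [read_edge_list]).
#' @param seed_genes character vector of seed gene ids.
#' @return sorted union of first neighbors, minus the seeds themselves.
#' @export
neighbor_genes <- function(graph, seed_genes) {
  present <- intersect(seed_genes, igraph::V(graph)$name)
  if (length(present) == 0) return(character(0))
  nb <- unique(unlist(lapply(present, function(g)
    igraph::neighbors(graph, g)$name)))
  sort(setdiff(nb, seed_genes))
}

#' DNB-neighbor DEGs for the contrasts up to the tipping point
#'
#' Intersects the PPI neighbors of the DNB module with the union of the DEG
#' sets of the listed contrasts (typically the later-vs-baseline contrasts
#' at and before the tipping point).
#'
#' @param neighbors character vector (see [neighbor_genes]).
#' @param deg_sets named list of per-contrast DEG gene vectors
#'   (see [call_degs]).
#' @param contrasts names of the contrasts to aggregate.
#' @return sorted gene-id vector.
#' @export
dnb_neighbor_degs <- function(neighbors, deg_sets, contrasts) {
  missing <- setdiff(contrasts, names(deg_sets))
  if (length(missing) > 0)
    dnb_stop("unknown_contrast", sprintf(
      "contrasts not in deg_sets: %s", paste(missing, collapse = ", ")))
  sort(intersect(neighbors, unique(unlist(deg_sets[contrasts]))))
}

#' Filter genes to those in any metastasis gene set
#'
#' @param genes character vector.
#' @param metastasis_sets a `gene_sets` collection (see [read_gmt]).
#' @return sorted intersection of `genes` with the union of all set members.
#' @export
metastasis_filter <- function(genes, metastasis_sets) {
  sort(intersect(genes, unique(unlist(metastasis_sets))))
}

# sample matrix on the chosen scope: pooled samples or timepoint means
scope_matrix <- function(series, sample_scope) {
  sample_scope <- match.arg(sample_scope, c("all_samples", "timepoint_means"))
  x <- if (sample_scope == "all_samples") series$values
       else timepoint_means(series)
  if (ncol(x) < 3)
    dnb_stop("too_few_replicates",
             "correlation p values need >= 3 samples in the chosen scope")
  x
}

# two-sided p for a Pearson r on n samples via t = r sqrt((n-2)/(1-r^2))
cor_p_value <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tval <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  ifelse(r2 >= 1, 0, p)
}

#' Correlation edges between two gene sets with significance filtering
#'
#' Pearson r for every (a, b) pair over the chosen sample space, with a
#' two-sided p from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 df. An edge
#' passes when |r| strictly exceeds `r_threshold` and p is strictly below
#' `p_threshold`. Genes with zero variance get r = 0, p = 1 for all their
#' pairs (with a warning). Pairs of a gene with itself are skipped.
#'
#' @param series an [expression_series].
#' @param set_a,set_b character vectors of gene ids present in the series.
#' @param r_threshold strict |r| cutoff (default 0.8).
#' @param p_threshold strict p cutoff (default 0.05).
#' @param sample_scope `"all_samples"` (timepoints x replicates pooled,
#'   default) or `"timepoint_means"`.
#' @return list with `edges` (data.frame gene_a, gene_b, r, p, passes) and
#'   `counts` (per-a-gene passing-partner counts, sorted decreasing with
#'   ties broken by gene id).
#' @export
correlate_gene_sets <- function(series, set_a, set_b, r_threshold = 0.8,
                                p_threshold = 0.05,
                                sample_scope = "all_samples") {
  x <- scope_matrix(series, sample_scope)
  missing <- setdiff(c(set_a, set_b), rownames(x))
  if (length(missing) > 0)
    dnb_stop("bad_module", sprintf(
      "genes not in series: %s", paste(missing, collapse = ", ")))
  n <- ncol(x)
  xa <- x[set_a, , drop = FALSE]
  xb <- x[set_b, , drop = FALSE]
  sda <- apply(xa, 1, stats::sd); sdb <- apply(xb, 1, stats::sd)
  if (any(c(sda, sdb) == 0))
    dnb_warn("zero-variance gene(s): their pairs get r = 0, p = 1")
  r <- suppressWarnings(stats::cor(t(xa), t(xb)))
  r[!is.finite(r)] <- 0
  r[sda == 0, ] <- 0
  r[, sdb == 0] <- 0
  p <- cor_p_value(r, n)
  p[sda == 0, ] <- 1
  p[, sdb == 0] <- 1
  grid <- expand.grid(gene_a = set_a, gene_b = set_b,
                      stringsAsFactors = FALSE)
  keep <- grid$gene_a != grid$gene_b
  edges <- data.frame(gene_a = grid$gene_a[keep], gene_b = grid$gene_b[keep],
                      r = as.vector(r)[keep], p = as.vector(p)[keep],
                      stringsAsFactors = FALSE)
  edges$passes <- abs(edges$r) > r_threshold & edges$p < p_threshold
  counts <- vapply(set_a, function(g)
    sum(edges$passes[edges$gene_a == g]), 0L)
  counts <- counts[order(-counts, names(counts))]
  list(edges = edges, counts = counts)
}

#' Per-sample pathway activity scores
#'
#' Each gene is z-scored across samples; a pathway's score in a sample is
#' the mean z of its member genes present in the series. Pathways with
#' fewer than 2 present members are dropped with a warning. This is a
#' transparent coordinated-expression score: it rises when member genes
#' move together above their own baselines.
#'
#' @param series an [expression_series].
#' @param pathway_sets a `gene_sets` collection.
#' @return list with `scores` (pathways x samples matrix) and `coverage`
#'   (present-member count per retained pathway).
#' @export
pathway_activity <- function(series, pathway_sets) {
  x <- series$values
  mu <- rowMeans(x); sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv == 0, 1, sdv)
  members <- lapply(pathway_sets, function(g) intersect(g, rownames(x)))
  cov <- lengths(members)
  if (any(cov < 2))
    dnb_warn(sprintf("dropping %d pathway(s) with < 2 members present",
                     sum(cov < 2)))
  keep <- cov >= 2
  if (!any(keep))
    dnb_stop("empty_set", "no pathway has >= 2 members in the series")
  scores <- do.call(rbind, lapply(members[keep], function(g)
    colMeans(z[g, , drop = FALSE])))
  rownames(scores) <- names(members)[keep]
  list(scores = scores, coverage = cov[keep])
}

#' Correlate DNB genes with pathway activity scores
#'
#' Pearson r between each DNB gene's expression and each pathway score
#' across all samples, with the same t-based p value and strict-threshold
#' flag as [correlate_gene_sets].
#'
#' @param series an [expression_series].
#' @param dnb_genes character vector of gene ids.
#' @param activities result of [pathway_activity].
#' @param r_threshold strict |r| cutoff (default 0.5).
#' @param p_threshold strict p cutoff (default 0.05).
#' @return data.frame with columns `gene`, `pathway`, `r`, `p`, `passes`.
#' @export
correlate_dnb_pathways <- function(series, dnb_genes, activities,
                                   r_threshold = 0.5, p_threshold = 0.05) {
  x <- series$values[dnb_genes, , drop = FALSE]
  s <- activities$scores
  n <- ncol(x)
  sdg <- apply(x, 1, stats::sd); sdp <- apply(s, 1, stats::sd)
  if (any(c(sdg, sdp) == 0))
    dnb_warn("zero-variance gene(s)/pathway(s): pairs get r = 0, p = 1")
  r <- suppressWarnings(stats::cor(t(x), t(s)))
  r[!is.finite(r)] <- 0
  r[sdg == 0, ] <- 0; r[, sdp == 0] <- 0
  p <- cor_p_value(r, n)
  p[sdg == 0, ] <- 1; p[, sdp == 0] <- 1
  out <- expand.grid(gene = dnb_genes, pathway = rownames(s),
                     stringsAsFactors = FALSE)
  out$r <- as.vector(r); out$p <- as.vector(p)
  out$passes <- abs(out$r) > r_threshold & out$p < p_threshold
  out
}

#' Dysregulation network between DNB genes and metastasis genes
#'
#' Correlation edges between the DNB module and metastasis-associated genes
#' that pass |r| > `r_threshold` and p < `p_threshold` (defaults 0.7 and
#' 0.05); export with [write_network_tsv].
#'
#' @param series an [expression_series].
#' @param dnb_genes,metastasis_genes character vectors of gene ids.
#' @param r_threshold,p_threshold strict cutoffs.
#' @param sample_scope see [correlate_gene_sets].
#' @return data.frame of passing edges (gene_a, gene_b, r, p, passes).
#' @export
build_dysregulation_network <- function(series, dnb_genes, metastasis_genes,
                                        r_threshold = 0.7,
                                        p_threshold = 0.05,
                                        sample_scope = "all_samples") {
  res <- correlate_gene_sets(series, dnb_genes, metastasis_genes,
                             r_threshold, p_threshold, sample_scope)
  res$edges[res$edges$passes, , drop = FALSE]
}
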