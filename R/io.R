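# Readers and writers for the package's plain-text formats: expression TSV +
# sample metadata, GMT gene sets, STRING-style edge lists and
# Cytoscape-importable correlation-network tables. TSV dialect throughout:
# tab-delimited, UTF-8, no quoting; empty or "." cells are errors rather than
# silent NAs.

#' Read an expression matrix with sample metadata
#'
#' The matrix file has a header row of sample ids and gene ids in the first
#' column; the metadata file maps each sample id to a timepoint and replicate
#' index. Timepoint order is the order of first appearance in the metadata
#' file.
#'
#' @param path path to the expression TSV.
#' @param metadata_path path to the metadata TSV (columns `sample`,
#'   `timepoint`, `replicate`).
#' @param log_transform apply `log2(x + 1)` on ingest (for raw-scale input).
#' @return an [expression_series].
#' @export
read_expression_tsv <- function(path, metadata_path, log_transform = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  if (anyDuplicated(raw[[1]]))
    dnb_stop("duplicate_gene", sprintf(
      "duplicate gene ids in %s: %s", path,
      paste(unique(raw[[1]][duplicated(raw[[1]])]), collapse = ", ")))
  genes <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) | cells == "" | cells == ".", arr.ind = TRUE)
  if (nrow(bad) > 0)
    dnb_stop("non_numeric", sprintf(
      "non-numeric cell '%s' at gene %s, sample %s",
      cells[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
      colnames(cells)[bad[1, 2]]))
  rownames(num) <- genes
  colnames(num) <- colnames(cells)
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            quote = "", colClasses = "character")
  meta$replicate <- as.integer(meta$replicate)
  expression_series(num, meta, log_transform = log_transform)
}

#' Write an expression series to TSV + metadata TSV
#'
#' Values are written with 17 significant digits so that read/write round
#' trips are bit-exact.
#'
#' @param series an [expression_series].
#' @param path,metadata_path output file paths.
#' @export
write_expression_tsv <- function(series, path, metadata_path) {
  if (nrow(series$values) == 0)
    dnb_stop("empty_series", "cannot write an expression series with no genes")
  vals <- apply(series$values, c(1, 2), function(x) sprintf("%.17g", x))
  header <- paste(c("gene", colnames(series$values)), collapse = "\t")
  rows <- paste(rownames(series$values),
                apply(vals, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, rows), path)
  meta <- series$sample_info[, c("sample", "timepoint", "replicate")]
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member genes.
#'
#' @param path path to the GMT file.
#' @return a `gene_sets` object: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3
  if (any(short))
    dnb_stop("malformed_gmt", sprintf(
      "GMT line %d has fewer than 3 fields", which(short)[1]))
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm))
    dnb_stop("duplicate_set", sprintf(
      "duplicate gene-set name: %s", nm[duplicated(nm)][1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  if (any(lengths(sets) == 0))
    dnb_stop("empty_set", "gene sets must be non-empty")
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2), nm)
  class(sets) <- "gene_sets"
  sets
}

#' Write a GMT gene-set file
#' @param sets a `gene_sets` object (or named list of character vectors).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)),
                                             names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets (sizes %s)\n", length(x),
              paste(utils::head(lengths(x), 10), collapse = ", ")))
  invisible(x)
}

#' Read a STRING-style PPI edge list
#'
#' Two id columns plus an optional integer score column (STRING convention,
#' 0-1000). The graph is undirected: duplicate and reversed pairs are
#' collapsed keeping the maximum score; self-loop rows are skipped with a
#' warning; edges below `min_score` are dropped.
#'
#' @param path path to the TSV edge list (header row).
#' @param score_column optional name of the score column.
#' @param min_score optional minimum score; edges strictly below it dropped.
#' @return a `ppi_graph`: an undirected [igraph::igraph] with vertex names
#'   and (if present) an edge attribute `score`.
#' @export
read_edge_list <- function(path, score_column = NULL, min_score = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (nrow(df) == 0) return(ppi_graph(character(0), character(0)))
  a <- df[[1]]; b <- df[[2]]
  score <- if (!is.null(score_column)) as.integer(df[[score_column]]) else NULL
  loops <- a == b
  if (any(loops)) {
    dnb_warn(sprintf("skipping %d self-loop row(s) in %s", sum(loops), path))
    a <- a[!loops]; b <- b[!loops]
    if (!is.null(score)) score <- score[!loops]
  }
  ppi_graph(a, b, score = score, min_score = min_score)
}

#' Construct a PPI graph from endpoint vectors
#'
#' @param from,to character vectors of edge endpoints.
#' @param score optional integer edge scores (0-1000).
#' @param nodes optional full node set (isolated nodes allowed).
#' @param min_score optional minimum score filter.
#' @return a `ppi_graph` (an undirected igraph with a `ppi_graph` class tag).
#' @export
ppi_graph <- function(from, to, score = NULL, nodes = NULL, min_score = NULL) {
  # canonical unordered pair -> dedupe keeping max score
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (!is.null(score)) {
    keep <- !duplicated(key)
    maxs <- tapply(score, key, max)
    lo <- lo[keep]; hi <- hi[keep]
    score <- as.integer(maxs[paste(lo, hi, sep = "\r")])
    if (!is.null(min_score)) {
      pass <- score >= min_score
      lo <- lo[pass]; hi <- hi[pass]; score <- score[pass]
    }
  } else {
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
  }
  verts <- unique(c(nodes, lo, hi))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  if (!is.null(score) && length(score) > 0)
    g <- igraph::set_edge_attr(g, "score", value = score)
  class(g) <- c("ppi_graph", class(g))
  g
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}

#' Write a correlation-edge table as a Cytoscape-importable network TSV
#'
#' Columns: source, target, interaction, r, p, passes. `r` and `p` are
#' written in scientific notation with 16 digits after the decimal point so
#' the file round-trips exactly.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `r`, `p`,
#'   `passes` (as returned by [correlate_gene_sets]).
#' @param path output path.
#' @param interaction interaction-type label for the third column.
#' @export
write_network_tsv <- function(edges, path, interaction = "correlation") {
  header <- paste(c("source", "target", "interaction", "r", "p", "passes"),
                  collapse = "\t")
  rows <- if (nrow(edges) == 0) character(0) else
    sprintf("%s\t%s\t%s\t%.16e\t%.16e\t%s",
            edges$gene_a, edges$gene_b, interaction, edges$r, edges$p,
            ifelse(edges$passes, "true", "false"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a network TSV written by [write_network_tsv]
#' @param path file path.
#' @return data.frame with columns gene_a, gene_b, r, p, passes.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  data.frame(gene_a = df$source, gene_b = df$target,
             r = as.numeric(df$r), p = as.numeric(df$p),
             passes = df$passes == "true", stringsAsFactors = FALSE)
}
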