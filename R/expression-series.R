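#' Replicated time-course expression series
#'
#' Container for a genes x samples matrix of log-scale expression measured at
#' ordered timepoints with replicates. This is the substrate for every
#' statistic in the package: differential expression contrasts, temporal
#' clustering and the per-timepoint module statistics (SD_in, PCC_in, PCC_out)
#' all draw their sample space from it.
#'
#' @param values numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns. Values are assumed log-scale and finite.
#' @param sample_info data.frame with columns `sample`, `timepoint`,
#'   `replicate`; one row per column of `values`, matched by `sample`.
#'   Timepoint order is taken from order of first appearance.
#' @param log_transform if `TRUE`, apply `log2(x + 1)` on construction for
#'   raw-scale inputs. Default `FALSE` (input already log scale).
#'
#' @return An object of class `expression_series`: a list with elements
#'   `values` (the matrix), `gene_ids`, `timepoints` (ordered labels) and
#'   `sample_info`.
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' si <- data.frame(sample = paste0("s", 1:6),
#'                  timepoint = rep(c("T1", "T2"), each = 3),
#'                  replicate = rep(1:3, 2))
#' es <- expression_series(m, si)
#' es
#' @export
expression_series <- function(values, sample_info, log_transform = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    dnb_stop("invalid_values", "'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    dnb_stop("invalid_values", "'values' must have gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    dnb_stop("duplicate_gene", sprintf(
      "duplicate gene ids: %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]),
            collapse = ", ")))
  req <- c("sample", "timepoint", "replicate")
  if (!all(req %in% names(sample_info)))
    dnb_stop("invalid_metadata", sprintf(
      "sample_info must contain columns: %s", paste(req, collapse = ", ")))
  sample_info$sample <- as.character(sample_info$sample)
  sample_info$timepoint <- as.character(sample_info$timepoint)
  if (is.null(colnames(values)))
    dnb_stop("invalid_values", "'values' must have sample ids as colnames")
  missing_meta <- setdiff(colnames(values), sample_info$sample)
  if (length(missing_meta) > 0)
    dnb_stop("metadata_mismatch", sprintf(
      "samples in matrix but missing from metadata: %s",
      paste(missing_meta, collapse = ", ")))
  sample_info <- sample_info[match(colnames(values), sample_info$sample), ,
                             drop = FALSE]
  rownames(sample_info) <- NULL
  if (log_transform) values <- log2(values + 1)
  if (!all(is.finite(values)))
    dnb_stop("non_finite", "expression values must all be finite")
  tps <- unique(sample_info$timepoint)
  reps <- table(sample_info$timepoint)
  if (any(reps < 2))
    dnb_stop("too_few_replicates", sprintf(
      "every timepoint needs >= 2 replicates; offending: %s",
      paste(names(reps)[reps < 2], collapse = ", ")))
  structure(list(values = values,
                 gene_ids = rownames(values),
                 timepoints = tps,
                 sample_info = sample_info),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression_series: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  reps <- table(factor(x$sample_info$timepoint, levels = x$timepoints))
  cat("timepoints:",
      paste(sprintf("%s (n=%d)", names(reps), as.integer(reps)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_series <- function(x) dim(x$values)

# Columns (sample ids) belonging to one timepoint, in stored order.
timepoint_samples <- function(series, timepoint) {
  if (!timepoint %in% series$timepoints)
    dnb_stop("unknown_timepoint",
             sprintf("timepoint '%s' not in series", timepoint))
  series$sample_info$sample[series$sample_info$timepoint == timepoint]
}

# Genes x timepoints matrix of per-timepoint replicate means.
timepoint_means <- function(series) {
  out <- vapply(series$timepoints, function(tp) {
    rowMeans(series$values[, timepoint_samples(series, tp), drop = FALSE])
  }, numeric(nrow(series$values)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(series$gene_ids, NULL))
  colnames(out) <- series$timepoints
  out
}

# classed conditions so callers/tests can distinguish error families
dnb_stop <- function(class, msg) {
  stop(structure(class = c(paste0("dnbtip_", class), "dnbtip_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

dnb_warn <- function(msg) warning(msg, call. = FALSE)
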