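# Per-contrast differential expression across timepoints. The test statistic
# is an empirical-Bayes variance-moderated two-group t: the per-gene pooled
# variance is shrunk toward a prior (default: the median gene variance) with
# prior_df pseudo-degrees of freedom, which stabilises the n-of-3 design the
# pipeline targets. Each contrast is fit independently (no shared design
# matrix or covariates).

#' Per-gene log2 fold change between two timepoints
#'
#' Mean log2 expression over numerator replicates minus mean over denominator
#' replicates (the series is log scale, so the difference of means is the
#' log2 fold change).
#'
#' @param series an [expression_series].
#' @param numerator,denominator timepoint labels (e.g. `"T4"`, `"T1"`).
#' @return named numeric vector, one value per gene.
#' @export
log2_fold_change <- function(series, numerator, denominator) {
  if (identical(numerator, denominator))
    dnb_stop("bad_contrast", "contrast timepoints must differ")
  num <- series$values[, timepoint_samples(series, numerator), drop = FALSE]
  den <- series$values[, timepoint_samples(series, denominator), drop = FALSE]
  rowMeans(num) - rowMeans(den)
}

#' Moderated two-group t statistic per gene
#'
#' Pooled two-group variance \eqn{s_g^2} with residual df \eqn{d = n_1+n_2-2}
#' is shrunk to \eqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)} where
#' \eqn{d_0} = `prior_df` and \eqn{s_0^2} = `prior_var` (default: median of
#' the per-gene pooled variances). The statistic is
#' \eqn{t = \mathrm{log2fc} / (\tilde s_g \sqrt{1/n_1 + 1/n_2})} with a
#' two-sided p value on \eqn{d_0 + d} degrees of freedom. `prior_df = 0`
#' reduces exactly to the classical pooled two-sample t.
#'
#' @param series an [expression_series].
#' @param numerator,denominator timepoint labels.
#' @param prior_df prior degrees of freedom d0 (>= 0).
#' @param prior_var prior variance s0^2; default median of gene variances.
#' @return data.frame with columns `gene`, `log2fc`, `t`, `p`.
#' @export
moderated_t <- function(series, numerator, denominator, prior_df = 4,
                        prior_var = NULL) {
  num <- series$values[, timepoint_samples(series, numerator), drop = FALSE]
  den <- series$values[, timepoint_samples(series, denominator), drop = FALSE]
  n1 <- ncol(num); n2 <- ncol(den)
  d <- n1 + n2 - 2
  if (d <= 0)
    dnb_stop("too_few_replicates",
             "moderated t needs >= 2 replicates per group in total df")
  lfc <- rowMeans(num) - rowMeans(den)
  ss1 <- rowSums((num - rowMeans(num))^2)
  ss2 <- rowSums((den - rowMeans(den))^2)
  s2 <- (ss1 + ss2) / d
  if (is.null(prior_var)) prior_var <- stats::median(s2)
  s2_tilde <- if (is.infinite(prior_df)) rep(prior_var, length(s2)) else
    (prior_df * prior_var + d * s2) / (prior_df + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  df_total <- if (is.infinite(prior_df)) Inf else prior_df + d
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  data.frame(gene = series$gene_ids, log2fc = lfc, t = tstat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust] with `method = "BH"`, kept as a named
#' operation so the adjustment rule used throughout the pipeline is explicit
#' and testable.
#'
#' @param p numeric vector of p values.
#' @return vector of BH-adjusted q values in input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Fit all later-vs-baseline contrasts
#'
#' Computes, for every timepoint after `baseline`, the log2 fold change,
#' moderated t, raw p and BH-adjusted q per gene, and calls DEGs at the
#' stated thresholds.
#'
#' @param series an [expression_series].
#' @param baseline baseline timepoint label (default: first timepoint).
#' @param contrasts optional character vector of numerator timepoints;
#'   default all timepoints after the baseline.
#' @inheritParams moderated_t
#' @inheritParams call_degs
#' @return a `deg_table`: data.frame with columns `gene`, `contrast`,
#'   `log2fc`, `t`, `p`, `q`, `is_deg`. BH adjustment is within contrast.
#' @examples
#' sim <- simulate_critical_transition(
#'   simulation_config(mean_shift = 2, seed = 3))
#' degs <- fit_degs(sim$series)
#' head(degs[degs$is_deg, ])
#' @export
fit_degs <- function(series, baseline = series$timepoints[1],
                     contrasts = NULL, prior_df = 4, prior_var = NULL,
                     lfc_threshold = 1.0, p_threshold = 0.05,
                     use_adjusted = FALSE) {
  if (!baseline %in% series$timepoints)
    dnb_stop("unknown_timepoint",
             sprintf("baseline timepoint '%s' not in series", baseline))
  if (is.null(contrasts)) {
    later <- which(series$timepoints == baseline) <
      seq_along(series$timepoints)
    contrasts <- series$timepoints[later]
  }
  res <- lapply(contrasts, function(tp) {
    tab <- moderated_t(series, tp, baseline, prior_df, prior_var)
    tab$contrast <- sprintf("%s/%s", tp, baseline)
    tab$q <- bh_adjust(tab$p)
    tab
  })
  out <- do.call(rbind, res)
  out <- out[, c("gene", "contrast", "log2fc", "t", "p", "q")]
  out$is_deg <- abs(out$log2fc) > lfc_threshold &
    (if (use_adjusted) out$q else out$p) < p_threshold
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes at thresholds
#'
#' A gene passes when |log2fc| strictly exceeds `lfc_threshold` and its p
#' (or BH q, if `use_adjusted`) is strictly below `p_threshold`.
#'
#' @param table a `deg_table` (from [fit_degs]) or any data.frame with
#'   columns `gene`, `contrast`, `log2fc`, `p`, `q`.
#' @param lfc_threshold |log2 fold change| cutoff (default 1).
#' @param p_threshold p (or q) cutoff (default 0.05).
#' @param use_adjusted use BH-adjusted q instead of raw p.
#' @return named list of gene-id character vectors, one per contrast.
#' @export
call_degs <- function(table, lfc_threshold = 1.0, p_threshold = 0.05,
                      use_adjusted = FALSE) {
  stat <- if (use_adjusted) table$q else table$p
  pass <- abs(table$log2fc) > lfc_threshold & stat < p_threshold
  split(table$gene[pass],
        factor(table$contrast[pass], levels = unique(table$contrast)))
}

#' Write a DEG table to TSV
#' @param table a `deg_table`.
#' @param path output path.
#' @export
write_deg_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
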