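# Dynamic network biomarker (DNB) core. A candidate gene module is scored at
# each timepoint by three statistics over that timepooint's replicates:
#   SD_in   mean per-gene standard deviation within the module,
#   PCC_in  mean |Pearson r| over all within-module gene pairs,
#   PCC_out mean |Pearson r| over all module x background gene pairs,
# combined into the criticality index CI = size * PCC_in * SD_in /
# (PCC_out + eps). A module approaching a critical transition shows rising
# SD_in and PCC_in and falling PCC_out, so CI peaks at the tipping point.
# The replicate set at a timepoint (n = 3 in the motivating design) is the
# sample space of every correlation; with so few replicates individual r
# values are noisy and only the module-level averages are meaningful.

# per-timepoint |correlation| matrix and replicate SDs, shared by all the
# module statistics; zero-variance genes get |r| = 0 against everything
tp_cor_sd <- function(series, timepoint, warn_zero_var = TRUE) {
  x <- series$values[, timepoint_samples(series, timepoint), drop = FALSE]
  if (ncol(x) < 3)
    dnb_stop("too_few_replicates", sprintf(
      "timepoint '%s' has %d replicates; correlations need >= 3",
      timepoint, ncol(x)))
  sds <- apply(x, 1, stats::sd)
  absR <- abs(suppressWarnings(stats::cor(t(x))))
  if (any(sds == 0)) {
    if (warn_zero_var)
      dnb_warn(sprintf(
        "%d gene(s) with zero replicate variance at %s contribute |r| = 0",
        sum(sds == 0), timepoint))
    absR[sds == 0, ] <- 0
    absR[, sds == 0] <- 0
  }
  absR[!is.finite(absR)] <- 0
  list(absR = absR, sds = sds)
}

stats_from_mats <- function(mats, mod_idx, timepoint) {
  S <- mats$absR[mod_idx, mod_idx, drop = FALSE]
  size <- length(mod_idx)
  out_idx <- setdiff(seq_len(nrow(mats$absR)), mod_idx)
  list(timepoint = timepoint,
       sd_in = mean(mats$sds[mod_idx]),
       pcc_in = mean(S[upper.tri(S)]),
       pcc_out = if (length(out_idx) > 0)
         mean(mats$absR[mod_idx, out_idx]) else 0,
       size = size)
}

#' Module statistics at one timepoint
#'
#' Computes SD_in (mean over module genes of the sample SD, denominator
#' n - 1, of the gene's replicate values), PCC_in (mean |r| over all
#' within-module gene pairs) and PCC_out (mean |r| over all module x
#' background pairs), with the replicates at `timepoint` as the sample
#' space. Pairs involving a gene with zero replicate variance contribute
#' |r| = 0 (with a warning).
#'
#' @param series an [expression_series].
#' @param module_genes character vector of module gene ids (>= 2).
#' @param timepoint timepoint label (>= 3 replicates required).
#' @return list with `timepoint`, `sd_in`, `pcc_in`, `pcc_out`, `size`.
#' @export
module_stats <- function(series, module_genes, timepoint) {
  if (length(module_genes) < 2)
    dnb_stop("bad_module", "module must contain >= 2 genes")
  missing <- setdiff(module_genes, series$gene_ids)
  if (length(missing) > 0)
    dnb_stop("bad_module", sprintf(
      "module genes not in series: %s", paste(missing, collapse = ", ")))
  mats <- tp_cor_sd(series, timepoint)
  stats_from_mats(mats, match(module_genes, series$gene_ids), timepoint)
}

#' Criticality index of a module at a timepoint
#'
#' \deqn{CI = w \cdot PCC_{in} \cdot SD_{in} / (PCC_{out} + \epsilon)}
#' with w = module size when `use_size_weight` (the default reading of the
#' size-weighted index) and w = 1 otherwise. The epsilon guard keeps the
#' index finite when the module is uncorrelated with the background.
#'
#' @param stats a list with `sd_in`, `pcc_in`, `pcc_out`, `size` (see
#'   [module_stats]).
#' @param use_size_weight include the module size factor (default TRUE).
#' @param epsilon additive guard on PCC_out (> 0, default 1e-6).
#' @return the CI, a non-negative number.
#' @examples
#' criticality_index(list(size = 2, pcc_in = 0.5, sd_in = 2, pcc_out = 0.25))
#' @export
criticality_index <- function(stats, use_size_weight = TRUE,
                              epsilon = 1e-6) {
  if (epsilon <= 0) dnb_stop("bad_config", "epsilon must be > 0")
  w <- if (use_size_weight) stats$size else 1
  w * stats$pcc_in * stats$sd_in / (stats$pcc_out + epsilon)
}

#' Candidate modules by correlation clustering
#'
#' Genes are clustered agglomeratively with distance 1 - |r| and the stated
#' linkage; the dendrogram is cut at each height in `cut_heights` and every
#' cluster whose size falls in [min_size, max_size] becomes a candidate. By
#' default r is computed over all samples pooled, which gives the
#' correlation the degrees of freedom that a single timepoint's few
#' replicates cannot (with n = 3 replicates the null |r| floor is 2/pi, so
#' per-timepoint clustering cannot separate a module from chance
#' alignment); pass `timepoint` to cluster on one timepoint's replicates
#' instead. Genes are sorted lexicographically before clustering so the
#' result is independent of input order; duplicate candidates are removed.
#'
#' @param series an [expression_series].
#' @param timepoint optional timepoint label; `NULL` (default) pools all
#'   samples.
#' @param min_size,max_size candidate size window (max defaults to half the
#'   gene count).
#' @param cut_heights dendrogram cut heights on the 1 - |r| scale.
#' @param linkage hclust agglomeration method.
#' @return list of character vectors (each sorted), possibly empty.
#' @export
candidate_modules <- function(series, timepoint = NULL, min_size = 5,
                              max_size = NULL,
                              cut_heights = c(0.3, 0.5, 0.7),
                              linkage = "complete") {
  if (is.null(max_size)) max_size <- max(min_size, nrow(series$values) %/% 2)
  if (is.null(timepoint)) {
    # two pooled correlation passes: raw (maximal df) and within-timepoint
    # centered (invariant to mean trajectories, so shared expression shifts
    # cannot masquerade as module covariance); candidates are pooled over
    # both
    centered <- series$values
    for (tp in series$timepoints) {
      j <- timepoint_samples(series, tp)
      centered[, j] <- centered[, j] -
        rowMeans(centered[, j, drop = FALSE])
    }
    mats <- lapply(list(series$values, centered), function(x) {
      sds <- apply(x, 1, stats::sd)
      absR <- abs(suppressWarnings(stats::cor(t(x))))
      absR[sds == 0, ] <- 0; absR[, sds == 0] <- 0
      absR[!is.finite(absR)] <- 0
      absR
    })
  } else {
    mats <- list(tp_cor_sd(series, timepoint, warn_zero_var = FALSE)$absR)
  }
  ord <- order(series$gene_ids)
  cands <- list()
  for (absR in mats) {
    absR <- absR[ord, ord]
    rownames(absR) <- colnames(absR) <- series$gene_ids[ord]
    diag(absR) <- 1
    hc <- stats::hclust(stats::as.dist(1 - absR), method = linkage)
    for (h in cut_heights) {
      cl <- stats::cutree(hc, h = h)
      for (k in unique(cl)) {
        members <- names(cl)[cl == k]
        if (length(members) >= min_size && length(members) <= max_size)
          cands[[paste(members, collapse = "\r")]] <- members
      }
    }
  }
  unname(cands)
}

#' Detect the tipping point and its dynamic network biomarker module
#'
#' The model-fitting entry point of the package. Candidate modules are
#' generated by pooled-sample correlation clustering ([candidate_modules])
#' and every candidate is scored by its criticality index at every
#' timepoint; the best-scoring (candidate, timepoint) pair is the detected
#' DNB and its tipping point (ties broken toward the earliest timepoint,
#' then the lexicographically smallest gene set). The winner's full CI
#' profile across all timepoints is reported, and the three DNB criteria
#' are flagged by comparing its tipping-timepoint statistics against all
#' other timepoints: SD_in and PCC_in must exceed the other timepoints'
#' maximum by at least the spread (SD) of those values, and PCC_out must
#' fall below their minimum by the same margin — a rise that merely tops
#' the list is not treated as a significant increase.
#'
#' Candidate selection uses a square-root-size-weighted criticality score:
#' the size-weighted CI grows roughly linearly in module size against the
#' fixed correlation noise floor of few-replicate data, so comparing it
#' across modules of different sizes systematically favours diluted
#' superclusters; weighting by sqrt(size) penalises dilution while still
#' rewarding larger coherent modules. All reported CI values (profile,
#' candidates table, permutation null) use the standard
#' [criticality_index] formula, and for a fixed module the tipping point is
#' the same under either weighting.
#'
#' @param series an [expression_series] with >= 2 timepoints.
#' @param min_size,max_size,cut_heights,linkage candidate-generation
#'   parameters (see [candidate_modules]).
#' @param use_size_weight,epsilon criticality-index parameters (see
#'   [criticality_index]).
#' @param selection_weight size weighting used only to compare candidate
#'   modules of different sizes during the search: `"sqrt_size"` (default),
#'   `"size"` (the reported CI itself) or `"none"`.
#' @param refine after selection, restrict the module to genes whose own
#'   replicate SD across timepoints peaks at the detected tipping point
#'   (the member-level counterpart of the SD_in criterion); skipped when
#'   fewer than `min_size` genes would remain. Default TRUE.
#' @param module_genes optional: skip the search and profile this module.
#' @param n_permutations if > 0, attach an empirical permutation p for the
#'   observed CI at the tipping point (see [permutation_null]).
#' @param seed RNG seed for the permutation null.
#' @return an object of class `dnb`: list with `module_genes`, `stats` (one
#'   row per timepoint: sd_in, pcc_in, pcc_out, size, ci),
#'   `tipping_timepoint`, `ci_peak`, `criteria` (named logicals
#'   `sd_in_increased`, `pcc_in_increased`, `pcc_out_decreased`),
#'   `candidates` (per-timepoint best-candidate table), `perm_p` and `call`.
#' @examples
#' sim <- simulate_critical_transition(simulation_config(seed = 1))
#' fit <- dnb_detect(sim$series)
#' fit
#' sim$truth$tipping_label
#' @seealso [summary.dnb], [plot.dnb], [permutation_null]
#' @export
dnb_detect <- function(series, min_size = 5, max_size = NULL,
                       cut_heights = c(0.3, 0.5, 0.7), linkage = "complete",
                       use_size_weight = TRUE, epsilon = 1e-6,
                       selection_weight = c("sqrt_size", "size", "none"),
                       refine = TRUE, module_genes = NULL,
                       n_permutations = 0, seed = 1) {
  selection_weight <- match.arg(selection_weight)
  if (length(series$timepoints) < 2)
    dnb_stop("bad_config", "tipping detection needs >= 2 timepoints")
  mats <- lapply(series$timepoints, function(tp) tp_cor_sd(series, tp))
  names(mats) <- series$timepoints

  cand_rows <- list()
  if (is.null(module_genes)) {
    cands <- candidate_modules(series, NULL, min_size, max_size,
                               cut_heights, linkage)
    if (length(cands) == 0)
      dnb_stop("no_candidates",
               "no candidate module in the size window at any cut height")
    keys <- vapply(cands, paste, "", collapse = "\r")
    sel_w <- switch(selection_weight,
                    sqrt_size = function(n) sqrt(n),
                    size = function(n) n,
                    none = function(n) 1)
    best <- NULL
    for (tp in series$timepoints) {
      sts <- lapply(cands, function(g)
        stats_from_mats(mats[[tp]], match(g, series$gene_ids), tp))
      cis <- vapply(sts, criticality_index, 0, use_size_weight, epsilon)
      scores <- vapply(sts, function(st)
        sel_w(st$size) * st$pcc_in * st$sd_in / (st$pcc_out + epsilon), 0)
      top <- order(-scores, keys)[1]
      cand_rows[[tp]] <- data.frame(
        timepoint = tp, size = length(cands[[top]]), ci = cis[top],
        genes = paste(cands[[top]], collapse = ","),
        stringsAsFactors = FALSE)
      if (is.null(best) || scores[top] > best$score)  # ties: earliest tp
        best <- list(genes = cands[[top]], score = scores[top],
                     timepoint = tp)
    }
    module_genes <- best$genes
    if (refine) {
      # greedy backward elimination under the same selection score: a gene
      # that dilutes the module (low SD, weak coupling at the tipping
      # point) is dropped when its removal raises the score; stops at a
      # local maximum or at min_size genes
      tip_mats <- mats[[best$timepoint]]
      score_of <- function(genes) {
        st <- stats_from_mats(tip_mats, match(genes, series$gene_ids),
                              best$timepoint)
        sel_w(st$size) * st$pcc_in * st$sd_in / (st$pcc_out + epsilon)
      }
      cur <- best$genes
      cur_score <- score_of(cur)
      repeat {
        if (length(cur) <= max(2, min_size)) break
        drop_scores <- vapply(seq_along(cur), function(i)
          score_of(cur[-i]), 0)
        i_best <- which.max(drop_scores)
        if (drop_scores[i_best] <= cur_score) break
        cur <- cur[-i_best]
        cur_score <- drop_scores[i_best]
      }
      # member-level counterpart of the SD_in criterion: a DNB member's own
      # replicate SD should peak at the tipping point
      sd_mat <- vapply(mats, function(m)
        m$sds[match(cur, series$gene_ids)], numeric(length(cur)))
      if (is.null(dim(sd_mat))) sd_mat <- matrix(sd_mat, nrow = 1)
      peaked <- sd_mat[, match(best$timepoint, series$timepoints)] ==
        apply(sd_mat, 1, max)
      if (sum(peaked) >= max(2, min_size)) cur <- cur[peaked]
      module_genes <- cur
    }
  } else {
    module_genes <- sort(module_genes)
  }

  idx <- match(module_genes, series$gene_ids)
  if (anyNA(idx))
    dnb_stop("bad_module", "module genes missing from series")
  prof <- do.call(rbind, lapply(series$timepoints, function(tp) {
    st <- stats_from_mats(mats[[tp]], idx, tp)
    data.frame(timepoint = tp, sd_in = st$sd_in, pcc_in = st$pcc_in,
               pcc_out = st$pcc_out, size = st$size,
               ci = criticality_index(st, use_size_weight, epsilon),
               stringsAsFactors = FALSE)
  }))
  tip_i <- which.max(prof$ci)          # which.max: earliest on ties
  tip <- prof$timepoint[tip_i]
  others <- prof[-tip_i, , drop = FALSE]
  # "significantly" increased/decreased: beyond the between-timepoint
  # spread of the remaining timepoints, not merely their max/min (a bare
  # extremum comparison fires too easily because the tipping timepoint is
  # itself chosen as the CI maximum)
  criteria <- c(
    sd_in_increased = prof$sd_in[tip_i] >
      max(others$sd_in) + stats::sd(others$sd_in),
    pcc_in_increased = prof$pcc_in[tip_i] >
      max(others$pcc_in) + stats::sd(others$pcc_in),
    pcc_out_decreased = prof$pcc_out[tip_i] <
      min(others$pcc_out) - stats::sd(others$pcc_out))
  perm_p <- NA_real_
  if (n_permutations > 0) {
    pn <- permutation_null(series, length(module_genes), tip,
                           B = n_permutations, seed = seed,
                           observed_ci = prof$ci[tip_i],
                           use_size_weight = use_size_weight,
                           epsilon = epsilon)
    perm_p <- pn$p
  }
  structure(list(module_genes = module_genes, stats = prof,
                 tipping_timepoint = tip, ci_peak = prof$ci[tip_i],
                 criteria = criteria,
                 candidates = if (length(cand_rows))
                   do.call(rbind, cand_rows) else NULL,
                 perm_p = perm_p,
                 params = list(min_size = min_size, max_size = max_size,
                               cut_heights = cut_heights, linkage = linkage,
                               use_size_weight = use_size_weight,
                               epsilon = epsilon),
                 call = match.call()),
            class = "dnb")
}

#' Permutation null for the criticality index
#'
#' Draws `B` random modules of `module_size` genes (uniformly, without
#' replacement within a draw) and computes each one's CI at `timepoint`.
#' The empirical p for an observed CI uses the add-one correction
#' \eqn{p = (1 + \#\{CI_{null} \ge CI_{obs}\}) / (B + 1)}.
#'
#' @param series an [expression_series].
#' @param module_size genes per null module (>= 2).
#' @param timepoint timepoint label.
#' @param B number of permutations (>= 1).
#' @param seed RNG seed.
#' @param observed_ci optional observed CI to convert into a p value.
#' @inheritParams criticality_index
#' @return list with `null_ci` (length B) and `p` (NA when no observed CI
#'   was supplied).
#' @export
permutation_null <- function(series, module_size, timepoint, B = 1000,
                             seed = 1, observed_ci = NULL,
                             use_size_weight = TRUE, epsilon = 1e-6) {
  if (B < 1) dnb_stop("bad_config", "B must be >= 1")
  if (module_size < 2) dnb_stop("bad_module", "module_size must be >= 2")
  mats <- tp_cor_sd(series, timepoint, warn_zero_var = FALSE)
  g <- nrow(series$values)
  null_ci <- with_seed(seed + 31L, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(g, module_size)
      criticality_index(stats_from_mats(mats, idx, timepoint),
                        use_size_weight, epsilon)
    }, 0)
  })
  p <- if (is.null(observed_ci)) NA_real_ else
    (1 + sum(null_ci >= observed_ci)) / (B + 1)
  list(null_ci = null_ci, p = p)
}

#' @export
print.dnb <- function(x, ...) {
  cat(sprintf("DNB fit: %d-gene module, tipping point at %s (CI = %.3f)\n",
              length(x$module_genes), x$tipping_timepoint, x$ci_peak))
  crit <- paste(names(x$criteria)[x$criteria], collapse = ", ")
  cat("criteria met:", if (nzchar(crit)) crit else "none", "\n")
  if (!is.na(x$perm_p)) cat(sprintf("permutation p = %.4g\n", x$perm_p))
  invisible(x)
}

#' Summarize a DNB fit
#' @param object a `dnb` object.
#' @param ... unused.
#' @return the object, invisibly, after printing the per-timepoint
#'   statistics table, criteria flags and module gene list.
#' @export
summary.dnb <- function(object, ...) {
  print(object)
  cat("\nper-timepoint statistics:\n")
  print(object$stats, row.names = FALSE, digits = 4)
  cat("\nmodule genes:\n")
  cat(strwrap(paste(object$module_genes, collapse = ", "), 76), sep = "\n")
  invisible(object)
}

#' Plot the CI profile of a DNB fit
#'
#' Line chart of the criticality index across timepoints with the detected
#' tipping point marked.
#'
#' @param x a `dnb` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.dnb <- function(x, ...) {
  n <- nrow(x$stats)
  graphics::plot(seq_len(n), x$stats$ci, type = "b", xaxt = "n",
                 xlab = "timepoint", ylab = "criticality index", ...)
  graphics::axis(1, at = seq_len(n), labels = x$stats$timepoint)
  tip <- which(x$stats$timepoint == x$tipping_timepoint)
  graphics::points(tip, x$stats$ci[tip], pch = 19, col = "red")
  graphics::abline(v = tip, lty = 2, col = "red")
  invisible(x)
}

#' Coefficients of a DNB fit: the per-timepoint CI profile
#' @param object a `dnb` object.
#' @param ... unused.
#' @return named numeric vector of CI values by timepoint.
#' @export
coef.dnb <- function(object, ...)
  stats::setNames(object$stats$ci, object$stats$timepoint)
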