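# Fuzzy c-means clustering of standardized temporal profiles (Bezdek's
# alternating-optimization algorithm). Clustering is descriptive in this
# pipeline: it characterises the expression patterns of the perturbed genes;
# tipping-point detection does not depend on it.

#' Standardize per-gene temporal profiles
#'
#' Per gene: average expression per timepoint across replicates, then
#' z-score across timepoints. Genes with zero temporal variance carry no
#' pattern information and are excluded (reported in the `"excluded"`
#' attribute).
#'
#' @param series an [expression_series].
#' @return genes x timepoints numeric matrix of z-scored profiles, with
#'   attribute `excluded` naming zero-variance genes.
#' @export
standardize_profiles <- function(series) {
  means <- timepoint_means(series)
  sds <- apply(means, 1, stats::sd)
  excluded <- rownames(means)[sds == 0]
  keep <- sds > 0
  prof <- (means[keep, , drop = FALSE] -
             rowMeans(means[keep, , drop = FALSE])) / sds[keep]
  attr(prof, "excluded") <- excluded
  prof
}

#' Fuzzy c-means clustering
#'
#' Alternates membership updates
#' \eqn{u_{ij} = 1 / \sum_l (d_{ij}/d_{il})^{2/(m-1)}} and centroid updates
#' \eqn{c_j = \sum_i u_{ij}^m x_i / \sum_i u_{ij}^m} (Euclidean distance)
#' until the objective \eqn{J_m = \sum_{ij} u_{ij}^m d_{ij}^2} changes by
#' less than `tol` or `max_iter` is reached. A profile coincident with a
#' centroid (zero distance) gets membership 1 there. Initial centroids are k
#' distinct profiles chosen by distance-weighted (k-means++-style) sampling;
#' pass `centroids` for a fully deterministic start. With `nstart > 1` the
#' run with the lowest final objective is kept.
#'
#' @param profiles genes x timepoints matrix (see [standardize_profiles]).
#' @param k number of clusters (default 4).
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed RNG seed for centroid initialization.
#' @param centroids optional k x timepoints matrix of starting centroids
#'   (overrides random initialization).
#' @param nstart number of random restarts (best objective kept).
#' @return a `fuzzy_clustering` object: list with `membership` (genes x k,
#'   rows sum to 1), `hard_label` (argmax cluster per gene, ties to the
#'   lowest index), `centroids` (k x timepoints) and `objective_trace`.
#' @examples
#' prof <- matrix(rnorm(200), 50, 4)
#' rownames(prof) <- paste0("g", 1:50)
#' fc <- fuzzy_cmeans(prof, k = 3, seed = 1)
#' table(fc$hard_label)
#' @export
fuzzy_cmeans <- function(profiles, k = 4, m = 2.0, tol = 1e-6,
                         max_iter = 500, seed = NULL, centroids = NULL,
                         nstart = 1) {
  if (k < 1) dnb_stop("bad_config", "k must be >= 1")
  if (m <= 1) dnb_stop("bad_config", "fuzzifier m must be > 1")
  distinct <- unique(profiles)
  if (nrow(distinct) < k)
    dnb_stop("bad_config", sprintf(
      "k = %d exceeds the %d distinct profiles", k, nrow(distinct)))
  if (!is.null(centroids))
    return(fcm_run(profiles, k, m, tol, max_iter, centroids))
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- with_seed(seed + s - 1, fcm_init(distinct, k))
    fit <- fcm_run(profiles, k, m, tol, max_iter, init)
    if (is.null(best) || utils::tail(fit$objective_trace, 1) <
          utils::tail(best$objective_trace, 1))
      best <- fit
  }
  best
}

# distance-weighted sampling of k distinct profiles as starting centroids
fcm_init <- function(distinct, k) {
  n <- nrow(distinct)
  idx <- sample.int(n, 1)
  while (length(idx) < k) {
    d2 <- vapply(seq_len(n), function(i) {
      min(colSums((t(distinct[idx, , drop = FALSE]) - distinct[i, ])^2))
    }, 0)
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    cand <- sample.int(n, 1, prob = prob)
    if (!cand %in% idx) idx <- c(idx, cand)
  }
  distinct[idx, , drop = FALSE]
}

fcm_run <- function(profiles, k, m, tol, max_iter, centroids) {
  centroids <- matrix(as.numeric(centroids), k, ncol(profiles))
  n <- nrow(profiles)
  trace <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- pairwise_sqdist(profiles, centroids)      # n x k
    u <- fcm_memberships(d2, m)
    um <- u^m
    centroids <- (t(um) %*% profiles) / colSums(um)
    d2 <- pairwise_sqdist(profiles, centroids)
    obj <- sum(um * d2)
    trace <- c(trace, obj)
    if (it > 1 && abs(trace[it - 1] - obj) < tol) break
  }
  hard <- apply(u, 1, which.max)   # which.max ties -> lowest index
  structure(list(membership = u, hard_label = hard, centroids = centroids,
                 objective_trace = trace),
            class = "fuzzy_clustering")
}

fcm_memberships <- function(d2, m) {
  pw <- 1 / (m - 1)
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 <= .Machine$double.eps
  any_zero <- rowSums(zero) > 0
  if (any(any_zero)) {
    # coincident point: full membership on the first zero-distance cluster
    first0 <- apply(zero[any_zero, , drop = FALSE], 1, which.max)
    u[cbind(which(any_zero), first0)] <- 1
  }
  if (any(!any_zero)) {
    inv <- (1 / d2[!any_zero, , drop = FALSE])^pw
    u[!any_zero, ] <- inv / rowSums(inv)
  }
  dimnames(u) <- dimnames(d2)
  u
}

pairwise_sqdist <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf(
    "fuzzy_clustering: %d profiles, %d clusters, %d iterations (J = %.4g)\n",
    nrow(x$membership), ncol(x$membership), length(x$objective_trace),
    utils::tail(x$objective_trace, 1)))
  cat("cluster sizes (hard):",
      paste(tabulate(x$hard_label, ncol(x$membership)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write clustering outputs as TSV
#' @param fit a `fuzzy_clustering`.
#' @param membership_path,centroid_path output paths.
#' @export
write_clustering_tsv <- function(fit, membership_path, centroid_path) {
  mem <- data.frame(gene = rownames(fit$membership),
                    cluster = fit$hard_label,
                    fit$membership, check.names = FALSE)
  colnames(mem)[-(1:2)] <- paste0("m", seq_len(ncol(fit$membership)))
  utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cen <- data.frame(cluster = seq_len(nrow(fit$centroids)), fit$centroids)
  utils::write.table(cen, centroid_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(membership_path, centroid_path))
}
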