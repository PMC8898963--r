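# Resampling consensus clustering of samples on a gene subset (typically the
# regulator panel), with CDF / delta-area model selection over k.

#' Consensus clustering over a range of k
#'
#' For each resample, a fraction of samples (and optionally genes) is drawn
#' without replacement, the subsample is clustered with the inner method, and
#' co-cluster / co-sample counts are accumulated. The consensus matrix entry
#' for a sample pair is (# times co-clustered) / (# times co-sampled). The
#' same resamples (and, for the hierarchical inner method, the same tree) are
#' reused across all requested k, as in the reference consensus-clustering
#' tool. Final assignment at each k is average-linkage hierarchical
#' clustering of `1 - consensus` cut at k.
#'
#' Per-resample RNG substreams are derived from the master seed by counter,
#' so results do not depend on evaluation order.
#'
#' @param expr expression matrix.
#' @param genes gene subset to cluster on (must be present in `expr`).
#' @param ks integer vector of consecutive k values starting at 2.
#' @param n_resamples number of resamples (>= 10).
#' @param sample_frac fraction of samples per resample (0, 1].
#' @param gene_frac fraction of `genes` per resample (0, 1].
#' @param inner inner clusterer: `"hclust"` (average linkage on
#'   1 - Pearson correlation; default) or `"kmeans"` (Euclidean, 10 restarts).
#' @param seed integer master seed.
#' @param store_resamples keep each resample's subsample indices and inner
#'   assignments (attribute `"resamples"` on the result list), for auditing
#'   the consensus recount.
#' @return list of `consensus_result` objects, one per k, each with elements
#'   `k`, `consensus`, `assignment` ([group_assignment()]), `cdf` (empirical
#'   CDF of upper-triangle consensus values on a 101-point grid), `auc`
#'   (trapezoid area under the CDF), and `n_never_cosampled`.
#' @export
consensus_sweep <- function(expr, genes, ks = 2:10, n_resamples = 1000,
                            sample_frac = 0.8, gene_frac = 1,
                            inner = c("hclust", "kmeans"), seed = 1,
                            store_resamples = FALSE) {
  inner <- match.arg(inner)
  validate_expression(expr)
  if (any(ks < 2L)) stop("k must be >= 2")
  if (n_resamples < 10L) stop("need n_resamples >= 10")
  if (sample_frac <= 0 || sample_frac > 1 || gene_frac <= 0 || gene_frac > 1)
    stop("sample_frac and gene_frac must be in (0, 1]")
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0L)
    stop("genes absent from expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  x <- expr[genes, , drop = FALSE]
  n <- ncol(x); m <- nrow(x)
  n_sub <- ceiling(sample_frac * n)
  m_sub <- ceiling(gene_frac * m)
  k_max <- max(ks)

  cocluster <- lapply(ks, function(k) matrix(0L, n, n))
  names(cocluster) <- as.character(ks)
  cosample <- matrix(0L, n, n)
  resample_log <- if (store_resamples) vector("list", n_resamples) else NULL

  for (r in seq_len(n_resamples)) {
    cl_list <- NULL
    for (attempt in seq_len(10L)) {
      set.seed(substream_seed(seed, (r - 1L) * 10L + attempt))
      idx_s <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
      idx_g <- if (m_sub < m) sort(sample.int(m, m_sub)) else seq_len(m)
      if (length(idx_s) < k_max) next  # redraw: too few samples to cut at k
      cl_list <- inner_cluster(x[idx_g, idx_s, drop = FALSE], ks, inner)
      break
    }
    if (is.null(cl_list))
      stop("could not draw a subsample with at least ", k_max,
           " samples in 10 attempts per resample")
    if (store_resamples)
      resample_log[[r]] <- list(samples = idx_s, genes = idx_g,
                                assignments = cl_list)
    cosample[idx_s, idx_s] <- cosample[idx_s, idx_s] + 1L
    for (k in ks) {
      cl <- cl_list[[as.character(k)]]
      same <- outer(cl, cl, "==") * 1L
      ck <- as.character(k)
      cocluster[[ck]][idx_s, idx_s] <- cocluster[[ck]][idx_s, idx_s] + same
    }
  }

  never <- cosample == 0 & upper.tri(cosample)
  n_never <- sum(never)
  if (n_never > 0L)
    warning(n_never, " sample pair(s) were never co-sampled; their consensus",
            " is set to 0")
  denom <- cosample
  denom[denom == 0L] <- 1L

  out <- lapply(ks, function(k) {
    cons <- cocluster[[as.character(k)]] / denom
    diag(cons) <- 1
    dimnames(cons) <- list(colnames(x), colnames(x))
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
    assign_k <- stats::cutree(hc, k = k)
    cc <- consensus_cdf(cons)
    structure(list(
      k = k, consensus = cons,
      assignment = group_assignment(colnames(x), paste0("CL", assign_k)),
      cdf = cc$cdf, grid = cc$grid, auc = cc$auc,
      n_never_cosampled = n_never), class = "consensus_result")
  })
  if (store_resamples) attr(out, "resamples") <- resample_log
  out
}

#' Consensus CDF and its area
#'
#' Empirical CDF of the upper-triangle entries of a consensus matrix on the
#' fixed 101-point grid over `[0, 1]`, and its trapezoid-rule area.
#'
#' @param consensus samples x samples consensus matrix.
#' @return list: `grid`, `cdf` (non-decreasing, ends at 1), `auc`.
#' @export
consensus_cdf <- function(consensus) {
  grid <- seq(0, 1, length.out = 101L)
  vals <- consensus[upper.tri(consensus)]
  cdf <- stats::ecdf(vals)(grid)
  list(grid = grid, cdf = cdf, auc = trapezoid_auc(grid, cdf))
}

#' Consensus clustering at a single k
#'
#' Convenience wrapper around [consensus_sweep()] for one k.
#'
#' @inheritParams consensus_sweep
#' @param k number of clusters (>= 2).
#' @return a single `consensus_result`.
#' @export
consensus_run <- function(expr, genes, k, n_resamples = 1000,
                          sample_frac = 0.8, gene_frac = 1,
                          inner = c("hclust", "kmeans"), seed = 1,
                          store_resamples = FALSE) {
  res <- consensus_sweep(expr, genes, ks = k, n_resamples = n_resamples,
                         sample_frac = sample_frac, gene_frac = gene_frac,
                         inner = inner, seed = seed,
                         store_resamples = store_resamples)
  out <- res[[1]]
  if (store_resamples) attr(out, "resamples") <- attr(res, "resamples")
  out
}

# cluster one subsample at every requested k; hclust builds one tree and
# cuts it at each k, kmeans runs independently per k
inner_cluster <- function(xsub, ks, inner) {
  if (inner == "hclust") {
    d <- cor_distance(xsub)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cuts <- stats::cutree(hc, k = ks)
    if (length(ks) == 1L) cuts <- matrix(cuts, ncol = 1L)
    out <- lapply(seq_along(ks), function(i) cuts[, i])
  } else {
    out <- lapply(ks, function(k)
      stats::kmeans(t(xsub), centers = k, nstart = 10L)$cluster)
  }
  names(out) <- as.character(ks)
  out
}

# 1 - Pearson correlation between samples across the gene subset; a gene
# subset with zero variance in some sample yields NA correlations -> treated
# as maximal distance
cor_distance <- function(xsub) {
  cc <- suppressWarnings(stats::cor(xsub))
  cc[!is.finite(cc)] <- 0
  1 - cc
}

#' CDF areas and delta-areas across k
#'
#' The area under each k's consensus CDF is computed by the trapezoid rule on
#' the 101-point grid over `[0, 1]`; the delta-area for `k > 2` is the
#' relative change `(auc_k - auc_{k-1}) / auc_{k-1}`, and for the smallest
#' k (2) it equals the area itself.
#'
#' @param results list of `consensus_result` ordered by k (consecutive,
#'   starting at 2).
#' @return data.frame with columns `k`, `auc`, `delta_area`.
#' @export
cdf_and_delta <- function(results) {
  ks <- vapply(results, function(r) r$k, 0L)
  if (ks[1] != 2L || any(diff(ks) != 1L))
    stop("results must cover consecutive k starting at 2")
  auc <- vapply(results, function(r) r$auc, 0)
  delta <- c(auc[1], diff(auc) / auc[-length(auc)])
  data.frame(k = ks, auc = auc, delta_area = delta)
}

#' Select the number of clusters from the delta-area table
#'
#' Returns the smallest k whose successor's relative delta-area falls below
#' `threshold`; if every delta stays at or above the threshold, `k_max` is
#' returned with a warning. The full table should be inspected alongside
#' (the reference analyses additionally weighed CDF shape and subgroup
#' balance).
#'
#' @param tab table from [cdf_and_delta()].
#' @param k_max largest k considered.
#' @param threshold relative delta-area cut-off (default 0.1).
#' @return selected k (integer).
#' @export
select_k <- function(tab, k_max = max(tab$k), threshold = 0.1) {
  stopifnot(all(c("k", "delta_area") %in% names(tab)))
  tab <- tab[tab$k <= k_max, , drop = FALSE]
  if (min(tab$k) != 2L) stop("table must start at k = 2")
  for (k in tab$k[-nrow(tab)]) {
    d_next <- tab$delta_area[tab$k == k + 1L]
    if (length(d_next) == 1L && d_next < threshold) return(as.integer(k))
  }
  warning("no k has a successor delta-area below ", threshold,
          "; returning k_max = ", k_max)
  as.integer(k_max)
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# counter-derived substream seed, kept inside 32-bit integer range
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647)
}
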