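# Single-sample gene-set enrichment (ssGSEA), the integrated running-sum
# variant: per sample, genes are ranked, and a set's score is the sum over
# all ranked positions of the gap between the weighted in-set and the uniform
# out-of-set cumulative step functions (not the max-deviation GSEA statistic).

#' ssGSEA enrichment scores
#'
#' Per sample, genes are ranked by expression (average ranks for ties) and
#' ordered descending. For a set S, with rank weights `|r|^alpha`,
#' `P_hit(i)` is the weighted fraction of S encountered up to position i,
#' `P_miss(i)` the uniform fraction of non-members encountered, and the
#' enrichment score is `sum_i [P_hit(i) - P_miss(i)]`. Rank-based, hence
#' invariant to monotone transforms of a sample's expression vector.
#'
#' Signatures are first restricted to the matrix's genes; sets left empty,
#' or spanning the whole gene universe (no out-of-set genes), are dropped
#' with a warning.
#'
#' @param expr expression matrix.
#' @param sigs a [signature_set()].
#' @param alpha rank-weighting exponent, >= 0 (default 0.25; 0 gives uniform
#'   weights).
#' @return `score_matrix`: numeric matrix signatures x samples with
#'   attributes `normalized` (FALSE) and `category` (if the input had one).
#' @export
ssgsea_score <- function(expr, sigs, alpha = 0.25) {
  validate_expression(expr)
  if (alpha < 0) stop("alpha must be >= 0")
  sigs <- restrict_signatures(sigs, expr)
  m <- nrow(expr)
  full <- lengths(sigs$sets) == m
  if (any(full)) {
    warning("dropping signature(s) covering every gene (no out-of-set genes): ",
            paste(names(sigs$sets)[full], collapse = ", "))
    if (all(full)) stop("no scorable signature left")
    sigs <- signature_set(sigs$sets[!full],
                          category = if (!is.null(sigs$category))
                            sigs$category[!full] else NULL,
                          name = sigs$name)
  }
  sets_idx <- lapply(sigs$sets, function(g) match(g, rownames(expr)))
  scores <- vapply(seq_len(ncol(expr)), function(s) {
    rnk <- rank(expr[, s], ties.method = "average")
    ord <- order(rnk, decreasing = TRUE)
    pos_of_gene <- match(seq_len(m), ord)  # position in the descending order
    w <- rnk[ord]^alpha
    vapply(sets_idx, function(idx) {
      inset <- logical(m)
      inset[pos_of_gene[idx]] <- TRUE
      hit_w <- ifelse(inset, w, 0)
      p_hit <- cumsum(hit_w) / sum(hit_w)
      p_miss <- cumsum(!inset) / (m - length(idx))
      sum(p_hit - p_miss)
    }, 0)
  }, numeric(length(sets_idx)))
  scores <- matrix(scores, nrow = length(sets_idx),
                   dimnames = list(names(sigs$sets), colnames(expr)))
  structure(scores, normalized = FALSE, category = sigs$category,
            class = c("score_matrix", class(scores)))
}

#' Zero-floor (min-max) normalization of a score matrix
#'
#' Per signature row, scores are mapped to `(x - min) / (max - min)` so the
#' minimum becomes exactly 0 and the maximum 1. Constant rows map to all-zero
#' with a warning. Idempotent on rows already spanning `[0, 1]`.
#'
#' @param sm `score_matrix` from [ssgsea_score()].
#' @return normalized `score_matrix` (attribute `normalized = TRUE`).
#' @export
floor_normalize <- function(sm) {
  stopifnot(is.matrix(sm), is.numeric(sm))
  rng <- t(apply(sm, 1L, range))
  span <- rng[, 2] - rng[, 1]
  const <- span == 0
  if (any(const)) {
    warning("constant score row(s) mapped to all-zero: ",
            paste(rownames(sm)[const], collapse = ", "))
    span[const] <- 1
  }
  out <- (sm - rng[, 1]) / span
  attributes(out) <- attributes(sm)
  attr(out, "normalized") <- TRUE
  out
}

#' Signature-score differences between sample groups
#'
#' Per signature: Wilcoxon rank-sum for 2 groups, Kruskal-Wallis for 3+;
#' two-sided p-values, Benjamini-Hochberg adjustment across signatures, and
#' star annotation at 0.05 / 0.01 / 0.001.
#'
#' @param sm `score_matrix`.
#' @param groups a [group_assignment()] covering the score samples.
#' @return data.frame: `signature`, one `mean_<group>` column per group,
#'   `statistic`, `p`, `q`, `stars`.
#' @export
group_score_test <- function(sm, groups) {
  lab <- group_labels_for(groups, colnames(sm))
  tab <- table(lab)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 samples")
  lev <- names(tab)
  res <- lapply(rownames(sm), function(sig) {
    x <- sm[sig, ]
    means <- tapply(x, lab, mean)
    if (length(lev) == 2L) {
      ht <- suppressWarnings(stats::wilcox.test(
        x[lab == lev[1]], x[lab == lev[2]],
        exact = !any(duplicated(x)) && length(x) <= 24L))
    } else {
      ht <- stats::kruskal.test(x, factor(lab))
    }
    c(means, statistic = unname(ht$statistic), p = ht$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out)[seq_along(lev)] <- paste0("mean_", lev)
  out <- cbind(signature = rownames(sm), out)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- stars_for(out$p)
  rownames(out) <- NULL
  out
}

#' Mean score per signature category
#'
#' Pro-tumor vs anti-tumor style category summaries: for each category label,
#' the per-sample mean of its member signatures' scores (linear in member
#' scores).
#'
#' @param sm `score_matrix` whose signatures carry a `category` attribute.
#' @return matrix categories x samples.
#' @export
category_mean_scores <- function(sm) {
  cat_lab <- attr(sm, "category")
  if (is.null(cat_lab)) stop("score matrix carries no signature categories")
  cat_lab <- cat_lab[rownames(sm)]
  cats <- unique(cat_lab)
  out <- t(vapply(cats, function(cc)
    colMeans(sm[cat_lab == cc, , drop = FALSE]), numeric(ncol(sm))))
  rownames(out) <- cats
  out
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
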