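# Dual-method differential expression between two sample groups on a
# continuous log-scale matrix: a variance-shrunk t test (method A) and a
# Wilcoxon rank-sum test (method B), each BH-adjusted, with DEGs called as
# the intersection of both methods' calls.

#' Differential expression between two groups
#'
#' Method A is a two-sample pooled-variance t statistic with the per-gene
#' pooled variance shrunk toward the grand median variance:
#' `s2_mod = (1 - w) * s2_g + w * median(s2)`, `w = n_genes / (n_genes + 50)`,
#' on `n1 + n2 - 2` degrees of freedom. Method B is the Wilcoxon rank-sum
#' test (exact enumeration when there are no ties and at most 12 values in
#' total; normal approximation with tie correction otherwise). `log_fc` is
#' the difference of group means (group2 - group1, groups in sorted label
#' order) on the log scale.
#'
#' @param expr expression matrix.
#' @param groups a [group_assignment()] with exactly 2 groups, each with at
#'   least 3 samples.
#' @return data.frame (`de_table`): `gene`, `log_fc`, `p_a`, `p_b`, `q_a`,
#'   `q_b`, `direction` (`up`/`down` by sign of `log_fc`).
#' @export
de_test <- function(expr, groups) {
  validate_expression(expr)
  lab <- group_labels_for(groups, colnames(expr))
  lev <- sort(unique(lab))
  if (length(lev) != 2L) stop("de_test requires exactly 2 groups")
  n1 <- sum(lab == lev[1]); n2 <- sum(lab == lev[2])
  if (min(n1, n2) < 3L) stop("each group needs at least 3 samples")
  x1 <- expr[, lab == lev[1], drop = FALSE]
  x2 <- expr[, lab == lev[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowVars(x1); v2 <- rowVars(x2)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  w <- nrow(expr) / (nrow(expr) + 50)
  s2_mod <- (1 - w) * s2 + w * stats::median(s2)
  tstat <- (m2 - m1) / sqrt(s2_mod * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p_a <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p_b <- vapply(seq_len(nrow(expr)), function(i)
    wilcox_p(x1[i, ], x2[i, ]), 0)
  out <- data.frame(gene = rownames(expr), log_fc = m2 - m1,
                    p_a = p_a, p_b = p_b,
                    q_a = stats::p.adjust(p_a, method = "BH"),
                    q_b = stats::p.adjust(p_b, method = "BH"),
                    direction = ifelse(m2 - m1 >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- lev
  class(out) <- c("de_table", "data.frame")
  out
}

# two-sided Wilcoxon rank-sum p: exact when tie-free and small, else normal
# approximation with tie correction (continuity-corrected)
wilcox_p <- function(x, y) {
  exact <- !any(duplicated(c(x, y))) && (length(x) + length(y)) <= 12L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

#' Call differentially expressed genes from a dual-method table
#'
#' The intersection rule: a gene is a DEG only if called by BOTH methods
#' (adjusted p below `alpha` each — or raw p with `use_adjusted = FALSE`)
#' AND `|log_fc| > lfc`. Monotone: shrinking `alpha` or growing `lfc` never
#' adds genes.
#'
#' @param de `de_table` from [de_test()].
#' @param alpha significance cut-off in (0, 1) (default 0.05).
#' @param lfc minimum absolute log fold change (default 1).
#' @param use_adjusted use BH-adjusted q-values (default) or raw p-values.
#' @return character vector of DEGs (in `de` order) with attribute
#'   `"direction"` (named `up`/`down` vector).
#' @export
call_degs <- function(de, alpha = 0.05, lfc = 1, use_adjusted = TRUE) {
  stopifnot(inherits(de, "de_table"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (lfc < 0) stop("lfc must be >= 0")
  pa <- if (use_adjusted) de$q_a else de$p_a
  pb <- if (use_adjusted) de$q_b else de$p_b
  keep <- pa < alpha & pb < alpha & abs(de$log_fc) > lfc
  genes <- de$gene[keep]
  structure(genes,
            direction = stats::setNames(de$direction[keep], genes))
}

#' Cross-cohort signature: ordered gene-list intersection
#'
#' Set intersection of two gene lists, in stable `list_1` order.
#'
#' @param list_1,list_2 character gene lists.
#' @return character vector.
#' @export
cross_cohort_signature <- function(list_1, list_2) {
  list_1[list_1 %in% list_2]
}
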