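# Correlation and group-association utilities used across the analysis
# (score vs phenotype panels, response-group comparisons).

#' Correlation coefficient with two-sided p
#'
#' Pearson or Spearman correlation. The p-value is the t-approximation for
#' `n > 9`; for `n <= 9` an exact permutation p is computed by enumerating
#' all `n!` orderings of `y` (two-sided, on |r|).
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `r`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, method = method, n = n))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  if (n <= 9L) {
    perms <- permutations_of(n)
    xc <- x - mean(x); yc <- y - mean(y)
    r_perm <- as.vector((matrix(yc[perms], nrow = nrow(perms)) %*% xc) /
                          (sqrt(sum(xc^2)) * sqrt(sum(yc^2))))
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
  } else {
    t_ <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(t_), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, method = method, n = n)
}

# all permutations of 1..n as a n! x n index matrix (n <= 9)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow = nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Score-covariate association panel
#'
#' Correlates the per-sample score with each covariate column and adjusts
#' across covariates by Benjamini-Hochberg; raw-p star annotations mirror
#' the usual figure convention.
#'
#' @param scores `score_vector` from [apply_score()].
#' @param covariates data.frame or matrix of numeric covariates with sample
#'   rownames.
#' @param method correlation method, see [correlate()].
#' @return data.frame: `covariate`, `r`, `p`, `q`, `stars`.
#' @export
score_association_panel <- function(scores, covariates,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates))) stop("covariates need sample rownames")
  idx <- match(scores$sample_id, rownames(covariates))
  if (anyNA(idx)) stop("covariates missing for some scored samples")
  covariates <- covariates[idx, , drop = FALSE]
  res <- lapply(colnames(covariates), function(cv) {
    ct <- correlate(scores$score, covariates[, cv], method = method)
    data.frame(covariate = cv, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- stars_for(out$p)
  out
}

#' Score differences between response groups
#'
#' Compares the score across response categories (Wilcoxon for 2 groups,
#' Kruskal-Wallis for 3+) and cross-tabulates the score's high/low group
#' against response with a chi-square test. Empty categories are dropped
#' with a warning.
#'
#' @param scores `score_vector` from [apply_score()].
#' @param response factor-like response per scored sample (e.g. CR/PR/SD/PD),
#'   in `scores$sample_id` order.
#' @return list: `medians` (named), `statistic`, `p`, `contingency`
#'   (score group x response), `chisq_p`.
#' @export
response_group_test <- function(scores, response) {
  if (length(response) != nrow(scores))
    stop("one response per scored sample required")
  response <- as.character(response)
  keep <- !is.na(response)
  response <- factor(response[keep])
  if (nlevels(response) != length(unique(response))) {
    warning("dropping empty response categories")
    response <- droplevels(response)
  }
  if (nlevels(response) < 2L) stop("need at least 2 response categories")
  s <- scores$score[keep]
  med <- tapply(s, response, stats::median)
  if (nlevels(response) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(
      s[response == levels(response)[1]],
      s[response == levels(response)[2]],
      exact = !any(duplicated(s)) && length(s) <= 24L))
  } else {
    ht <- stats::kruskal.test(s, response)
  }
  tab <- table(group = scores$group[keep], response = response)
  chi_p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab)$p.value),
    error = function(e) NA_real_)
  list(medians = med, statistic = unname(ht$statistic), p = ht$p.value,
       contingency = tab, chisq_p = chi_p)
}
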