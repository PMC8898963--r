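# The per-sample m6Ascore: univariate-Cox prognostic filtering of a signature
# gene list, correlation PCA of the filtered genes, and the standardized
# per-sample PC1 + PC2 projection sum, score = [sum(PC1g + PC2g) - X] / SD,
# where X and SD are the training-cohort mean and SD of the raw sums. A
# median split of the scored cohort defines high/low groups.

#' Filter signature genes by univariate Cox prognostic significance
#'
#' Each gene's expression enters a univariate Cox proportional-hazards model
#' against the aligned survival; genes with Wald p below `alpha` (raw p by
#' default; BH-adjusted with `adjust = TRUE`) are retained.
#'
#' @param genes candidate signature genes (present in `expr`).
#' @param expr expression matrix.
#' @param surv a [survival_table()] aligned to `expr` (see
#'   [align_samples()]).
#' @param alpha significance cut-off (default 0.05).
#' @param adjust apply BH adjustment across genes before thresholding.
#' @return character vector of retained genes with attribute `"cox_table"`
#'   (data.frame: gene, beta, HR, p, q).
#' @export
prognostic_filter <- function(genes, expr, surv, alpha = 0.05, adjust = FALSE) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss) > 0L)
    stop("genes absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (!identical(colnames(expr), surv$sample_id))
    stop("expression and survival are not aligned; call align_samples() first")
  ss <- survival::Surv(surv$time, surv$event)
  fits <- lapply(genes, function(g) {
    fit <- survival::coxph(ss ~ x, data = data.frame(x = expr[g, ]))
    sm <- summary(fit)$coefficients
    c(beta = sm[1, "coef"], p = sm[1, "Pr(>|z|)"])
  })
  tab <- as.data.frame(do.call(rbind, fits))
  tab <- data.frame(gene = genes, beta = tab$beta, HR = exp(tab$beta),
                    p = tab$p, q = stats::p.adjust(tab$p, method = "BH"),
                    stringsAsFactors = FALSE)
  crit <- if (adjust) tab$q else tab$p
  kept <- genes[crit < alpha]
  if (length(kept) == 0L)
    stop("no gene passes the prognostic filter at alpha = ", alpha,
         "; rerun with a larger alpha")
  structure(kept, cox_table = tab)
}

#' Fit the PCA score model on a training cohort
#'
#' Signature genes are standardized per gene (centered, unit variance) across
#' the training samples; the first two right singular directions of the
#' standardized genes x samples matrix give per-sample PC scores; the raw
#' per-sample score is `PC1 + PC2`, and the model stores the training mean
#' `X` and standard deviation `SD` of the raw scores, so training-cohort
#' scores have mean 0 and SD 1 by construction. A rank-1 matrix falls back to
#' PC1 only with a warning.
#'
#' @param expr expression matrix (training cohort).
#' @param genes signature genes (>= 2, present in `expr`).
#' @return object of class `score_model`: `genes`, `center`, `scale`,
#'   `loadings` (genes x 1-2, unit-norm columns), `X`, `SD`,
#'   `train_scores` (standardized, named by sample).
#' @export
fit_score_model <- function(expr, genes) {
  miss <- setdiff(genes, rownames(expr))
  if (length(miss) > 0L)
    stop("genes absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(genes) < 2L) stop("need at least 2 signature genes")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  x <- expr[genes, , drop = FALSE]
  ctr <- rowMeans(x)
  scl <- sqrt(rowVars(x))
  if (any(scl == 0))
    stop("constant signature gene(s): ",
         paste(genes[scl == 0], collapse = ", "))
  z <- (x - ctr) / scl                 # genes x samples, standardized
  sv <- svd(t(z))                      # samples as observations
  rank_ <- sum(sv$d > max(sv$d) * 1e-10)
  n_pc <- min(2L, rank_)
  if (n_pc < 2L)
    warning("standardized matrix has rank 1; falling back to PC1 only")
  loadings <- sv$v[, seq_len(n_pc), drop = FALSE]
  rownames(loadings) <- genes
  colnames(loadings) <- paste0("PC", seq_len(n_pc))
  # canonical per-column sign (largest-|loading| gene positive, ties broken
  # by gene name) so fitted scores do not depend on gene or sample order
  for (j in seq_len(n_pc)) {
    ord <- order(-abs(loadings[, j]), genes)
    if (loadings[ord[1], j] < 0) loadings[, j] <- -loadings[, j]
  }
  raw <- rowSums(t(z) %*% loadings)
  X <- mean(raw); SD <- stats::sd(raw)
  if (SD == 0) stop("degenerate score model: raw scores are constant")
  model <- structure(list(genes = genes, center = ctr, scale = scl,
                          loadings = loadings, X = X, SD = SD,
                          train_scores = stats::setNames((raw - X) / SD,
                                                         colnames(expr))),
                     class = "score_model")
  model
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model: %d genes, %d PC(s), X = %.4g, SD = %.4g\n",
              length(x$genes), ncol(x$loadings), x$X, x$SD))
  invisible(x)
}

#' Score a cohort with a fitted score model
#'
#' New samples are centered and scaled by the model's stored training
#' parameters, projected on the stored loadings, summed over PCs, and
#' standardized by the stored training `X`/`SD` (a true out-of-sample
#' transform). With `restandardize = TRUE` the scored cohort's own mean/SD
#' are used instead (per-cohort re-standardization). The high/low group is a
#' median split of the scored cohort (ties at the median go to `"low"`)
#' unless a fixed `cutoff` is supplied.
#'
#' @param model a `score_model`.
#' @param expr expression matrix containing every model gene.
#' @param cutoff optional fixed score cut-off for the high/low split.
#' @param restandardize re-standardize scores within this cohort.
#' @return data.frame of class `score_vector`: `sample_id`, `score`, `group`.
#' @export
apply_score <- function(model, expr, cutoff = NULL, restandardize = FALSE) {
  stopifnot(inherits(model, "score_model"))
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss) > 0L)
    stop("model gene(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  z <- (expr[model$genes, , drop = FALSE] - model$center) / model$scale
  raw <- rowSums(t(z) %*% model$loadings)
  score <- if (restandardize) (raw - mean(raw)) / stats::sd(raw)
           else (raw - model$X) / model$SD
  cut <- if (is.null(cutoff)) stats::median(score) else cutoff
  out <- data.frame(sample_id = colnames(expr), score = unname(score),
                    group = ifelse(score <= cut, "low", "high"),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  attr(out, "cutoff") <- cut
  out
}

#' Orient the score model so higher scores mean higher hazard
#'
#' PCA loadings carry an arbitrary joint sign. The model's training scores
#' enter a univariate Cox fit against the supplied survival; if the
#' coefficient is negative, the loadings (and `X`) are jointly negated so
#' the oriented score associates positively with hazard. Deterministic, and
#' idempotent on an already hazard-positive model.
#'
#' @param model a `score_model` fitted on the cohort that `surv` describes.
#' @param surv a [survival_table()] covering the model's training samples.
#' @return oriented `score_model`.
#' @export
sign_orient <- function(model, surv) {
  stopifnot(inherits(model, "score_model"))
  idx <- match(names(model$train_scores), surv$sample_id)
  if (anyNA(idx))
    stop("survival table lacks training samples: ",
         paste(utils::head(names(model$train_scores)[is.na(idx)], 5),
               collapse = ", "))
  df <- data.frame(time = surv$time[idx], event = surv$event[idx],
                   s = unname(model$train_scores))
  beta <- survival::coxph(survival::Surv(time, event) ~ s, data = df)$coef[[1]]
  if (beta < 0) {
    model$loadings <- -model$loadings
    model$X <- -model$X
    model$train_scores <- -model$train_scores
  }
  model
}
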