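# Simplified weighted co-expression module detection on a DEG submatrix:
# soft-threshold selection against scale-free fit, unsigned topological
# overlap, average-linkage module detection with a static tree cut,
# eigengenes, eigengene merging at a correlation cut, module-trait
# correlation, gene significance and module membership, hub genes.

#' Pick the soft-threshold power for a scale-free co-expression network
#'
#' For each candidate power, the unsigned adjacency is `|cor(i, j)|^power`,
#' connectivity `k_i = sum_{j != i} a_ij`, and the scale-free fit is the r^2
#' of `log10(freq(k))` on `log10(k)` over 10 connectivity bins, signed by
#' the negative of the slope sign. The chosen power is the smallest with
#' signed r^2 >= `r2_cut`, else the argmax.
#'
#' @param expr expression matrix (genes x samples); >= 30 genes recommended
#'   (warns below).
#' @param powers candidate integer powers.
#' @param r2_cut signed scale-free r^2 target (default 0.85).
#' @return list: `beta` (chosen power), `fit` (data.frame power,
#'   signed_r2, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                                r2_cut = 0.85) {
  validate_expression(expr)
  if (nrow(expr) < 30L)
    warning("fewer than 30 genes; scale-free fit is unreliable")
  v <- rowVars(expr)
  if (any(v == 0))
    stop("constant gene(s) must be filtered before network construction: ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- do.call(rbind, lapply(powers, function(p) {
    k <- rowSums(ac^p)
    sf <- scale_free_fit(k)
    data.frame(power = p, signed_r2 = sf["signed_r2"], slope = sf["slope"],
               mean_k = mean(k))
  }))
  rownames(fit) <- NULL
  ok <- fit$power[fit$signed_r2 >= r2_cut]
  beta <- if (length(ok) > 0L) min(ok) else fit$power[which.max(fit$signed_r2)]
  list(beta = as.integer(beta), fit = fit)
}

# r^2 of log10 freq vs log10 k over 10 connectivity bins, signed -sign(slope)
scale_free_fit <- function(k, n_bins = 10L) {
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mid <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(mid) & mid > 0
  if (sum(keep) < 3L) return(c(signed_r2 = 0, slope = 0))
  lx <- log10(mid[keep]); ly <- log10(freq[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2]]
  c(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix from an unsigned adjacency
#'
#' Standard unsigned TOM:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj`, diagonal 1. Symmetric with entries in
#' `[0, 1]`.
#'
#' @param adjacency symmetric genes x genes matrix in `[0, 1]`, diagonal 1.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a                       # sum_u a_iu a_uj, u free (a_ii = 0)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules
#'
#' Unsigned adjacency `|cor|^beta`, TOM dissimilarity, average-linkage tree,
#' static cut at `cut_height` times the tree's maximum merge height (so the
#' cut adapts to the overall density of the network); candidate clusters
#' below `min_module_size` go to `"grey"` (unassigned). Each module's eigengene is the first principal
#' component of its standardized expression, unit variance, sign-oriented to
#' correlate positively with the module's mean expression profile. Module
#' pairs whose eigengenes correlate above `merge_cut` are merged iteratively
#' (most-correlated pair first) until none remain.
#'
#' @param expr expression matrix (the DEG submatrix).
#' @param beta soft-threshold power (>= 1).
#' @param min_module_size smallest retained module (default 30).
#' @param merge_cut eigengene correlation above which modules merge
#'   (default 0.75).
#' @param cut_height static tree-cut height, as a fraction of the maximum
#'   merge height of the TOM-dissimilarity dendrogram (default 0.99).
#' @return object of class `module_result`: `beta`, `module_of` (named gene
#'   -> label, `"grey"` = unassigned), `eigengenes` (modules x samples),
#'   `expr`, plus empty slots filled by [module_trait()].
#' @export
detect_modules <- function(expr, beta, min_module_size = 30,
                           merge_cut = 0.75, cut_height = 0.99) {
  validate_expression(expr)
  if (beta < 1) stop("beta must be >= 1")
  ac <- abs(stats::cor(t(expr)))^beta
  diag(ac) <- 1
  tom <- tom_similarity(ac)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height * max(hc$height))
  sizes <- table(cl)
  good <- names(sizes)[sizes >= min_module_size]
  module_of <- rep("grey", nrow(expr))
  names(module_of) <- rownames(expr)
  for (i in seq_along(good))
    module_of[cl == as.integer(good[i])] <- paste0("M", i)
  if (all(module_of == "grey")) {
    warning("no module reaches min_module_size; all genes unassigned")
    return(structure(list(beta = beta, module_of = module_of,
                          eigengenes = NULL, expr = expr,
                          module_trait_r = NULL, module_trait_p = NULL,
                          gs = NULL, mm = NULL), class = "module_result"))
  }
  eg <- compute_eigengenes(expr, module_of)
  # iterative merge of the most-correlated eigengene pair above merge_cut
  repeat {
    mods <- rownames(eg)
    if (length(mods) < 2L) break
    cc <- stats::cor(t(eg))
    diag(cc) <- -Inf
    if (max(cc) <= merge_cut) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    keep <- mods[min(ij)]; drop_ <- mods[max(ij)]
    module_of[module_of == drop_] <- keep
    eg <- compute_eigengenes(expr, module_of)
  }
  # relabel modules consecutively by size
  mods <- setdiff(unique(module_of), "grey")
  mods <- mods[order(-tabulate(factor(module_of[module_of != "grey"],
                                      levels = mods)))]
  relabel <- stats::setNames(paste0("M", seq_along(mods)), mods)
  module_of[module_of != "grey"] <- relabel[module_of[module_of != "grey"]]
  eg <- compute_eigengenes(expr, module_of)
  structure(list(beta = beta, module_of = module_of, eigengenes = eg,
                 expr = expr, module_trait_r = NULL, module_trait_p = NULL,
                 gs = NULL, mm = NULL),
            class = "module_result")
}

# first PC (unit variance over samples) of each module's standardized
# expression, oriented to correlate positively with module mean expression
compute_eigengenes <- function(expr, module_of) {
  mods <- setdiff(sort(unique(module_of)), "grey")
  eg <- t(vapply(mods, function(mod) {
    x <- expr[names(module_of)[module_of == mod], , drop = FALSE]
    z <- (x - rowMeans(x)) / sqrt(rowVars(x))
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- sv$u[, 1]
    e <- e / stats::sd(e)
    if (stats::cor(e, colMeans(x)) < 0) e <- -e
    e
  }, numeric(ncol(expr))))
  rownames(eg) <- mods
  colnames(eg) <- colnames(expr)
  eg
}

#' Correlate modules and genes with sample traits
#'
#' Fills a `module_result` with: eigengene-trait Pearson r and two-sided p;
#' gene significance GS (per-gene absolute Pearson correlation with each
#' trait); module membership MM (per-gene Pearson correlation with its own
#' module's eigengene; NA for grey genes). Constant traits give NA columns
#' with a warning.
#'
#' @param mr `module_result` from [detect_modules()].
#' @param traits data.frame or matrix, samples x traits (rownames = sample
#'   ids matching the expression matrix).
#' @return `module_result` with `module_trait_r`, `module_trait_p`, `gs`,
#'   `mm` filled.
#' @export
module_trait <- function(mr, traits) {
  stopifnot(inherits(mr, "module_result"))
  if (is.null(mr$eigengenes)) stop("module result has no modules")
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)))
    stop("traits need sample rownames")
  idx <- match(colnames(mr$expr), rownames(traits))
  if (anyNA(idx)) stop("traits missing for some samples")
  traits <- traits[idx, , drop = FALSE]
  const <- apply(traits, 2L, function(t) stats::sd(t) == 0)
  if (any(const))
    warning("constant trait(s), correlations undefined: ",
            paste(colnames(traits)[const], collapse = ", "))
  n <- nrow(traits)
  r <- suppressWarnings(stats::cor(t(mr$eigengenes), traits))
  p <- cor_p(r, n)
  gs <- abs(suppressWarnings(stats::cor(t(mr$expr), traits)))
  mm <- rep(NA_real_, nrow(mr$expr))
  names(mm) <- rownames(mr$expr)
  for (mod in rownames(mr$eigengenes)) {
    genes <- names(mr$module_of)[mr$module_of == mod]
    mm[genes] <- as.vector(stats::cor(t(mr$expr[genes, , drop = FALSE]),
                                      mr$eigengenes[mod, ]))
  }
  mr$module_trait_r <- r
  mr$module_trait_p <- p
  mr$gs <- gs
  mr$mm <- mm
  mr
}

# two-sided p for a Pearson correlation via the t transform
cor_p <- function(r, n) {
  t_ <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t_), df = n - 2, lower.tail = FALSE)
}

#' Hub genes of a module
#'
#' Genes of the module with gene significance for `trait` at or above
#' `gs_min` and module membership at or above `mm_min`.
#'
#' @param mr `module_result` filled by [module_trait()].
#' @param module module label.
#' @param trait trait name.
#' @param gs_min gene-significance threshold (default 0.2).
#' @param mm_min module-membership threshold (default 0.8).
#' @return character vector of hub genes.
#' @export
hub_genes <- function(mr, module, trait, gs_min = 0.2, mm_min = 0.8) {
  stopifnot(inherits(mr, "module_result"))
  if (is.null(mr$gs)) stop("call module_trait() first")
  if (!module %in% mr$module_of) stop("no such module: ", module)
  genes <- names(mr$module_of)[mr$module_of == module]
  genes[mr$gs[genes, trait] >= gs_min & mr$mm[genes] >= mm_min]
}
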