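make_block_expr <- function(sep = 20, n_per_block = 5, n_genes = 12,
                            seed = 5) {
  set.seed(seed)
  base1 <- rnorm(n_genes)
  base2 <- base1 + sep * rep_len(c(1, -1), n_genes)
  x <- cbind(
    matrix(rep(base1, n_per_block), ncol = n_per_block) +
      matrix(rnorm(n_genes * n_per_block, sd = 0.01), ncol = n_per_block),
    matrix(rep(base2, n_per_block), ncol = n_per_block) +
      matrix(rnorm(n_genes * n_per_block, sd = 0.01), ncol = n_per_block))
  dimnames(x) <- list(sprintf("g%02d", 1:n_genes),
                      sprintf("s%02d", 1:(2 * n_per_block)))
  x
}

test_that("perfectly separated blocks give a near-binary consensus", {
  x <- make_block_expr()
  res <- consensus_run(x, rownames(x), k = 2, n_resamples = 100, seed = 9)
  block <- rep(1:2, each = 5)
  within <- res$consensus[outer(block, block, "==") & upper.tri(res$consensus)]
  between <- res$consensus[outer(block, block, "!=")]
  expect_true(all(within >= 0.99))
  expect_true(all(between <= 0.01))
  expect_gt(ari(res$assignment$label, block), 0.999)
})

test_that("consensus matrix equals a brute-force recount of stored resamples", {
  x <- toy_expr(10, 8, seed = 13)
  res <- consensus_run(x, rownames(x), k = 2, n_resamples = 25, seed = 3,
                       store_resamples = TRUE)
  log <- attr(res, "resamples")
  n <- ncol(x)
  co <- matrix(0, n, n); tot <- matrix(0, n, n)
  for (rs in log) {
    idx <- rs$samples
    cl <- rs$assignments[["2"]]
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      tot[idx[i], idx[j]] <- tot[idx[i], idx[j]] + 1
      if (cl[i] == cl[j]) co[idx[i], idx[j]] <- co[idx[i], idx[j]] + 1
    }
  }
  expected <- ifelse(tot > 0, co / pmax(tot, 1), 0)
  diag(expected) <- 1
  dimnames(expected) <- dimnames(res$consensus)
  expect_equal(res$consensus, expected, tolerance = 0)
})

test_that("full-sample deterministic resampling yields a 0/1 consensus equal to the single inner run", {
  x <- make_block_expr()
  res <- consensus_run(x, rownames(x), k = 2, n_resamples = 10,
                       sample_frac = 1, gene_frac = 1, seed = 4)
  expect_true(all(res$consensus %in% c(0, 1)))
  d <- as.dist(1 - cor(x))
  single <- cutree(hclust(d, method = "average"), k = 2)
  expect_equal(ari(res$assignment$label, single), 1)
})

test_that("consensus is invariant to sample permutation (deterministic configuration)", {
  x <- make_block_expr(sep = 3, seed = 8)
  perm <- c(4, 9, 1, 7, 2, 10, 5, 3, 8, 6)
  r1 <- consensus_run(x, rownames(x), k = 2, n_resamples = 10,
                      sample_frac = 1, gene_frac = 1, seed = 1)
  r2 <- consensus_run(x[, perm], rownames(x), k = 2, n_resamples = 10,
                      sample_frac = 1, gene_frac = 1, seed = 1)
  expect_equal(r2$consensus, r1$consensus[perm, perm], tolerance = 0)
})

test_that("CDF area matches analytic and fine-grid oracles", {
  # ideal binary consensus: auc = 1 - p up to grid resolution
  n <- 20
  for (p_ones in c(0.2, 0.5, 0.8)) {
    cons <- diag(n)
    ut <- which(upper.tri(cons))
    set.seed(1)
    ones <- sample(ut, round(p_ones * length(ut)))
    cons[ones] <- 1
    cons <- pmax(cons, t(cons))
    p_actual <- mean(cons[upper.tri(cons)] == 1)
    cc <- consensus_cdf(cons)
    expect_lt(abs(cc$auc - (1 - p_actual)), 0.01)
  }

  # random consensus: 101-point trapezoid within 0.01 of fine integration
  set.seed(2)
  cons <- matrix(runif(36), 6, 6)
  cons[lower.tri(cons)] <- t(cons)[lower.tri(cons)]
  diag(cons) <- 1
  cc <- consensus_cdf(cons)
  fine <- seq(0, 1, length.out = 100001)
  f <- ecdf(cons[upper.tri(cons)])(fine)
  auc_fine <- sum(diff(fine) * (head(f, -1) + tail(f, -1)) / 2)
  expect_equal(cc$auc, auc_fine, tolerance = 0.01)
  expect_true(all(diff(cc$cdf) >= 0))
  expect_equal(cc$cdf[101], 1)
})

test_that("delta-area table and k selection follow the stated rules", {
  x <- make_block_expr()
  res <- consensus_sweep(x, rownames(x), ks = 2:4, n_resamples = 20, seed = 2)
  tab <- cdf_and_delta(res)
  expect_equal(tab$delta_area[1], tab$auc[1])
  expect_equal(tab$delta_area[2], (tab$auc[2] - tab$auc[1]) / tab$auc[1])
  expect_error(cdf_and_delta(res[c(1, 3)]), "consecutive")

  # identical consensus at successive k -> delta 0
  r2 <- res[[2]]
  r_dup <- res[[3]]
  r_dup$auc <- r2$auc
  expect_equal(cdf_and_delta(list(res[[1]], r2, r_dup))$delta_area[3], 0)

  tab1 <- data.frame(k = 2:4, delta_area = c(0.60, 0.05, 0.04))
  expect_equal(select_k(tab1), 2L)
  tab2 <- data.frame(k = 2:4, delta_area = c(0.5, 0.3, 0.05))
  expect_equal(select_k(tab2), 3L)
  tab3 <- data.frame(k = 2:4, delta_area = c(0.5, 0.4, 0.3))
  expect_warning(k <- select_k(tab3), "k_max")
  expect_equal(k, 4L)
})

test_that("consensus run validates its inputs", {
  x <- toy_expr(6, 8)
  expect_error(consensus_run(x, rownames(x), k = 1, n_resamples = 10), "k")
  expect_error(consensus_run(x, rownames(x), k = 2, n_resamples = 5),
               "n_resamples")
  expect_error(consensus_run(x, c("g01", "nope"), k = 2, n_resamples = 10),
               "absent")
})
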