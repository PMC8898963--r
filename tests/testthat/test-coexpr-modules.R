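# two correlated gene blocks plus background noise
block_module_expr <- function(n_samples = 60, block = 20, noise = 20,
                              seed = 5, sd_within = 0.2) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  x <- rbind(
    t(sapply(1:block, function(i) f1 + rnorm(n_samples, sd = sd_within))),
    t(sapply(1:block, function(i) f2 + rnorm(n_samples, sd = sd_within))),
    matrix(rnorm(noise * n_samples), nrow = noise))
  dimnames(x) <- list(c(sprintf("b1_%02d", 1:block), sprintf("b2_%02d", 1:block),
                        sprintf("nz_%02d", 1:noise)),
                      sprintf("s%03d", 1:n_samples))
  x
}

test_that("TOM matches a direct transcription of its formula", {
  set.seed(2)
  cc <- abs(cor(matrix(rnorm(200), ncol = 10)))  # 20x20? no: 10 genes
  a <- cc^4
  diag(a) <- 1
  tom <- tom_similarity(a)
  n <- nrow(a)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { oracle[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(unname(tom), oracle, tolerance = 1e-12)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, n))
})

test_that("soft-threshold selection reports a fit table and honors forcing", {
  x <- block_module_expr()
  res <- pick_soft_threshold(x, powers = c(2, 4, 6, 8))
  expect_true(res$beta %in% c(2, 4, 6, 8))
  expect_equal(nrow(res$fit), 4)
  # mean connectivity decreases monotonically with power
  expect_true(all(diff(res$fit$mean_k) < 0))
  # connectivity recomputed directly from the adjacency definition
  a4 <- abs(cor(t(x)))^4
  diag(a4) <- 0
  expect_equal(res$fit$mean_k[res$fit$power == 4], mean(rowSums(a4)),
               tolerance = 1e-12)
  # forcing a single power returns it regardless of fit
  expect_equal(pick_soft_threshold(x, powers = 12)$beta, 12L)

  x_const <- x; x_const[1, ] <- 5
  expect_error(pick_soft_threshold(x_const, powers = 2), "constant")
})

test_that("module detection separates planted blocks and respects merge_cut", {
  x <- block_module_expr()
  mr <- detect_modules(x, beta = 6, min_module_size = 10, merge_cut = 0.75)
  mods <- setdiff(unique(mr$module_of), "grey")
  expect_equal(length(mods), 2L)
  b1 <- mr$module_of[grep("^b1", names(mr$module_of))]
  b2 <- mr$module_of[grep("^b2", names(mr$module_of))]
  expect_equal(length(unique(b1)), 1L)
  expect_equal(length(unique(b2)), 1L)
  expect_false(unique(b1) == unique(b2))
  # eigengenes unit variance, oriented with module mean expression
  for (mod in mods) {
    expect_equal(sd(mr$eigengenes[mod, ]), 1, tolerance = 1e-9)
    genes <- names(mr$module_of)[mr$module_of == mod]
    expect_gt(cor(mr$eigengenes[mod, ], colMeans(x[genes, ])), 0)
  }

  # merge_cut = 1 -> no merging even with correlated modules
  set.seed(9)
  f <- rnorm(60)
  xx <- rbind(t(sapply(1:12, function(i) f + rnorm(60, sd = 0.3))),
              t(sapply(1:12, function(i) f + rnorm(60, sd = 0.3))))
  dimnames(xx) <- list(sprintf("g%02d", 1:24), sprintf("s%03d", 1:60))
  m_nomerge <- detect_modules(xx, beta = 6, min_module_size = 5,
                              merge_cut = 1.0)
  m_merge <- detect_modules(xx, beta = 6, min_module_size = 5,
                            merge_cut = 0.75)
  expect_gte(length(setdiff(unique(m_nomerge$module_of), "grey")),
             length(setdiff(unique(m_merge$module_of), "grey")))
})

test_that("eigengene orientation cancels the SVD sign ambiguity", {
  x <- block_module_expr(seed = 21)
  mr <- detect_modules(x, beta = 6, min_module_size = 10)
  mr_neg <- detect_modules(-x, beta = 6, min_module_size = 10)
  # negating all inputs flips the eigengene with its module mean, so the
  # doubly-negated eigengene equals the original
  for (mod in setdiff(unique(mr$module_of), "grey")) {
    genes <- names(mr$module_of)[mr$module_of == mod]
    mod2 <- unique(mr_neg$module_of[genes])
    expect_length(mod2, 1L)
    expect_equal(unname(-mr_neg$eigengenes[mod2, ]),
                 unname(mr$eigengenes[mod, ]), tolerance = 1e-9)
  }
})

test_that("module-trait correlation matches the covariance formula and flags degenerate traits", {
  x <- block_module_expr(n_samples = 5, block = 6, noise = 4, seed = 33)
  mr <- detect_modules(x, beta = 2, min_module_size = 3, cut_height = 0.999)
  skip_if(is.null(mr$eigengenes), "no module found on tiny fixture")
  set.seed(1)
  traits <- matrix(rnorm(10), ncol = 2,
                   dimnames = list(colnames(x), c("t1", "t2")))
  mr <- module_trait(mr, traits)
  for (mod in rownames(mr$eigengenes)) for (tr in c("t1", "t2")) {
    e <- mr$eigengenes[mod, ]; t_ <- traits[, tr]
    r_oracle <- sum((e - mean(e)) * (t_ - mean(t_))) /
      sqrt(sum((e - mean(e))^2) * sum((t_ - mean(t_))^2))
    expect_equal(mr$module_trait_r[mod, tr], r_oracle, tolerance = 1e-12)
  }

  # trait equal to an eigengene: r = 1, p ~ 0
  x2 <- block_module_expr(seed = 44)
  mr2 <- detect_modules(x2, beta = 6, min_module_size = 10)
  tr2 <- cbind(self = mr2$eigengenes[1, ])
  rownames(tr2) <- colnames(x2)
  mr2 <- module_trait(mr2, tr2)
  expect_equal(unname(mr2$module_trait_r[1, "self"]), 1, tolerance = 1e-9)
  expect_lt(mr2$module_trait_p[1, "self"], 1e-20)

  tr3 <- cbind(flat = rep(1, ncol(x2)))
  rownames(tr3) <- colnames(x2)
  expect_warning(module_trait(mr2, tr3), "constant trait")
})

test_that("immune and stemness programs land in different modules on synthetic cohorts", {
  ch <- generate_cohort(150, 200, 12, delta = 3, program_size = 30,
                        noise_sd = 1, seed = 77)
  genes <- c(ch$truth$program_genes$immune, ch$truth$program_genes$stemness)
  mr <- detect_modules(ch$expr[genes, ], beta = 6, min_module_size = 10,
                       merge_cut = 0.75)
  prog <- ifelse(genes %in% ch$truth$program_genes$immune, "imm", "stem")
  expect_gt(ari(mr$module_of[genes], prog), 0.8)
})

test_that("hub-gene extraction follows the GS/MM thresholds", {
  x <- block_module_expr(seed = 55)
  # plant a hub: one gene nearly equal to block 1's shared factor
  mr <- detect_modules(x, beta = 6, min_module_size = 10)
  mod1 <- mr$module_of[["b1_01"]]
  genes1 <- names(mr$module_of)[mr$module_of == mod1]
  hub_truth <- x[genes1[1], ]
  traits <- cbind(drive = hub_truth + rnorm(ncol(x), sd = 0.05))
  rownames(traits) <- colnames(x)
  mr <- module_trait(mr, traits)

  # thresholds of 0 return the whole module, impossible thresholds nothing
  expect_setequal(hub_genes(mr, mod1, "drive", 0, 0), genes1)
  expect_length(hub_genes(mr, mod1, "drive", 1.01, 1.01), 0)
  # the planted driver gene always qualifies at the default thresholds
  expect_true(genes1[1] %in% hub_genes(mr, mod1, "drive"))
  expect_error(hub_genes(mr, "M99", "drive"), "no such module")
})
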