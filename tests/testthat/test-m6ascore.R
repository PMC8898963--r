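scored_cohort <- function(n = 200, seed = 51, beta_surv = 0.7) {
  ch <- generate_cohort(n, 150, 10, delta = 3, program_size = 25,
                        noise_sd = 1, beta_surv = beta_surv, seed = seed)
  sv <- generate_survival(ch$truth, 0.1, 0.3, seed = seed + 1)
  al <- suppressMessages(align_samples(ch$expr, sv))
  list(ch = ch, expr = al$expr, surv = al$surv)
}

test_that("prognostic filter keeps hazard-linked genes and behaves at the extremes", {
  sc <- scored_cohort(300, seed = 61)
  genes <- c(sc$ch$truth$regulator_genes[1:5], "GENE0001", "GENE0002")
  kept_all <- prognostic_filter(genes, sc$expr, sc$surv, alpha = 1)
  expect_setequal(as.character(kept_all), genes)
  tab <- attr(kept_all, "cox_table")
  expect_equal(tab$HR, exp(tab$beta))

  # a gene equal to the latent hazard covariate is retained
  x2 <- rbind(sc$expr, latent = sc$surv$z)
  kept <- prognostic_filter(c("latent", "GENE0001"), x2, sc$surv,
                            alpha = 0.05)
  expect_true("latent" %in% kept)

  expect_error(prognostic_filter("GENE0001", sc$expr, sc$surv, alpha = 1e-12),
               "larger alpha")
})

test_that("pure-noise genes pass the prognostic filter at about the alpha rate", {
  ps <- unlist(lapply(1:10, function(s) {
    sc <- scored_cohort(150, seed = 70 + s, beta_surv = 0)
    noise <- grep("^GENE", rownames(sc$expr), value = TRUE)[1:40]
    kept <- prognostic_filter(noise, sc$expr, sc$surv, alpha = 1)
    attr(kept, "cox_table")$p
  }))
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps < 0.05), 0.01)
})

test_that("score model reproduces an independent step-by-step SVD pipeline", {
  set.seed(3)
  x <- matrix(rnorm(12), nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  m <- fit_score_model(x, c("a", "b", "c"))

  # oracle: center, scale, SVD, project, sum, standardize - written out,
  # with each singular direction given the documented sign convention
  # (largest-|loading| gene positive, ties by gene name)
  z <- t(scale(t(x)))
  sv <- svd(t(z))
  v <- sv$v[, 1:2]
  for (j in 1:2) {
    ord <- order(-abs(v[, j]), rownames(x))
    if (v[ord[1], j] < 0) v[, j] <- -v[, j]
  }
  proj <- t(z) %*% v
  raw <- rowSums(proj)
  oracle <- (raw - mean(raw)) / sd(raw)
  got <- apply_score(m, x)$score
  expect_equal(got, unname(oracle), tolerance = 1e-10)
  expect_equal(vapply(1:2, function(j) sum(m$loadings[, j]^2), 0), c(1, 1),
               tolerance = 1e-10)
})

test_that("training scores are standardized and apply_score is consistent", {
  sc <- scored_cohort()
  genes <- rownames(sc$expr)[1:30]
  m <- fit_score_model(sc$expr, genes)
  expect_equal(mean(m$train_scores), 0, tolerance = 1e-9)
  expect_equal(sd(m$train_scores), 1, tolerance = 1e-9)

  svec <- apply_score(m, sc$expr)
  expect_equal(svec$score, unname(m$train_scores), tolerance = 1e-10)

  # duplicated samples score identically
  dup <- cbind(sc$expr, sc$expr)
  colnames(dup) <- c(colnames(sc$expr), paste0(colnames(sc$expr), "_copy"))
  sdup <- apply_score(m, dup)
  n <- ncol(sc$expr)
  expect_equal(sdup$score[1:n], sdup$score[(n + 1):(2 * n)])

  # median split: ties at the median go low; low holds ceiling(n/2)
  expect_equal(sum(svec$group == "low"), ceiling(nrow(svec) / 2))
  expect_error(apply_score(m, sc$expr[-1, ]), "missing")
})

test_that("the score is invariant to gene order, sample order, and per-gene affine maps", {
  sc <- scored_cohort(100, seed = 81)
  genes <- rownames(sc$expr)[1:20]
  m <- fit_score_model(sc$expr, genes)
  base <- apply_score(m, sc$expr)$score

  m_g <- fit_score_model(sc$expr[rev(rownames(sc$expr)), ], rev(genes))
  expect_equal(apply_score(m_g, sc$expr)$score, base, tolerance = 1e-9)

  perm <- sample(ncol(sc$expr))
  m_s <- fit_score_model(sc$expr[, perm], genes)
  expect_equal(apply_score(m_s, sc$expr)$score, base, tolerance = 1e-9)

  # shift one gene by a constant, rescale another positively
  x2 <- sc$expr
  x2[genes[1], ] <- x2[genes[1], ] + 100
  x2[genes[2], ] <- x2[genes[2], ] * 7
  m_a <- fit_score_model(x2, genes)
  expect_equal(apply_score(m_a, x2)$score, base, tolerance = 1e-9)
})

test_that("rank-1 expression collapses to a single informative direction", {
  set.seed(9)
  latent <- rnorm(40)
  x <- outer(c(1, 2, -1, 0.5), latent) +
    matrix(rnorm(160, sd = 1e-4), nrow = 4)
  dimnames(x) <- list(paste0("g", 1:4), paste0("s", 1:40))
  m <- fit_score_model(x, rownames(x))
  s <- apply_score(m, x)$score
  expect_gt(abs(cor(s, latent)), 0.99)
})

test_that("sign orientation makes the score hazard-positive and is stable", {
  sc <- scored_cohort(250, seed = 91)
  genes <- c(sc$ch$truth$program_genes$stemness,
             sc$ch$truth$program_genes$immune)
  m <- fit_score_model(sc$expr, genes)
  m_or <- sign_orient(m, sc$surv)
  df <- transform(sc$surv, s = unname(m_or$train_scores))
  expect_gt(cox_fit(df, "s")$table$HR, 1)

  # idempotent on an already-oriented model
  m_or2 <- sign_orient(m_or, sc$surv)
  expect_identical(m_or2$loadings, m_or$loadings)

  # negating the loadings before orientation changes nothing after it
  m_neg <- m
  m_neg$loadings <- -m_neg$loadings
  m_neg$X <- -m_neg$X
  m_neg$train_scores <- -m_neg$train_scores
  m_neg_or <- sign_orient(m_neg, sc$surv)
  expect_equal(m_neg_or$loadings, m_or$loadings, tolerance = 1e-12)
  expect_equal(apply_score(m_neg_or, sc$expr)$score,
               apply_score(m_or, sc$expr)$score, tolerance = 1e-12)

  # high/low split tracks the latent pattern; the PC2 component carries
  # pattern-orthogonal program noise, so agreement is averaged over cohorts
  aris <- vapply(91:95, function(s) {
    sc_i <- scored_cohort(250, seed = s)
    genes_i <- c(sc_i$ch$truth$regulator_genes,
                 sc_i$ch$truth$program_genes$stemness,
                 sc_i$ch$truth$program_genes$immune)
    m_i <- sign_orient(fit_score_model(sc_i$expr, genes_i), sc_i$surv)
    sv_i <- apply_score(m_i, sc_i$expr)
    ari(sv_i$group, sc_i$ch$truth$pattern[sv_i$sample_id])
  }, 0)
  expect_gt(mean(aris), 0.8)
})
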