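test_that("Kaplan-Meier matches the hand product-limit estimate", {
  sv <- survival_table(c("a", "b", "c"), time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_fit(sv)$all
  expect_equal(km$table$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median_survival, 2)

  # Greenwood standard errors against the hand formula
  set.seed(5)
  sv2 <- survival_table(paste0("s", 1:10), time = sample(1:20, 10),
                        event = rbinom(10, 1, 0.7))
  km2 <- km_fit(sv2)$all
  oracle <- greenwood_se(sv2$time, sv2$event)
  expect_equal(km2$table$survival, oracle$surv, tolerance = 1e-9)
  expect_equal(km2$table$std_err, oracle$se, tolerance = 1e-9)

  # no events: flat curve at 1, undefined median
  sv3 <- survival_table(c("a", "b"), time = c(1, 2), event = c(0, 0))
  w <- capture_warnings(km3 <- km_fit(sv3))
  expect_match(w, "no events", all = FALSE)
  expect_equal(nrow(km3$all$table), 0)
  expect_true(is.na(km3$all$median_survival))

  # duplicating every subject leaves S(t) unchanged
  sv4 <- survival_table(paste0("s", 1:6),
                        time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 1), 2))
  expect_equal(km_fit(sv4)$all$table$survival, c(2 / 3, 1 / 3, 0),
               tolerance = 1e-12)

  # invariant to input row order
  perm <- c(3, 1, 4, 2, 5, 9, 7, 10, 8, 6)
  km2p <- km_fit(sv2[perm, ])$all
  expect_equal(km2p$table, km2$table, tolerance = 1e-12)
})

test_that("log-rank chi-square matches a direct O-E/V transcription", {
  sv <- survival_table(paste0("s", 1:6), time = c(1, 2, 3, 4, 5, 6),
                       event = rep(1, 6))
  g <- group_assignment(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  lr <- logrank(sv, g)
  expect_equal(lr$chi2, logrank_brute(sv$time, sv$event, rep(c("A", "B"), each = 3)),
               tolerance = 1e-12)
  expect_equal(lr$df, 1L)

  # identical event/censor patterns in both groups -> chi2 = 0, p = 1
  sv2 <- survival_table(paste0("s", 1:6), time = rep(c(2, 5, 7), 2),
                        event = rep(c(1, 0, 1), 2))
  g2 <- group_assignment(paste0("s", 1:6), rep(c("A", "B"), 3))
  lr2 <- logrank(sv2, g2)
  expect_equal(lr2$chi2, 0, tolerance = 1e-9)
  expect_equal(lr2$p, 1, tolerance = 1e-9)

  # randomized instances against the oracle
  set.seed(12)
  for (i in 1:5) {
    n <- 14
    svr <- survival_table(paste0("s", 1:n),
                          time = sample(1:30, n), event = rbinom(n, 1, 0.8))
    lab <- sample(rep(c("A", "B"), each = n / 2))
    expect_equal(logrank(svr, group_assignment(svr$sample_id, lab))$chi2,
                 logrank_brute(svr$time, svr$event, lab), tolerance = 1e-9)
  }

  expect_error(logrank(sv, group_assignment(paste0("s", 1:6), rep("A", 6))),
               "2 groups")
})

test_that("log-rank agrees with the Cox score test at beta = 0", {
  set.seed(31)
  n <- 40
  sv <- survival_table(paste0("s", 1:n), time = rexp(n), event = rep(1, n))
  lab <- rep(c("A", "B"), each = n / 2)
  lr <- logrank(sv, group_assignment(sv$sample_id, lab))
  df <- transform(sv, x = as.integer(lab == "B"))
  sct <- summary(cox_fit(df, "x")$fit)$sctest[["test"]]
  expect_equal(lr$chi2, sct, tolerance = 1e-6)
})

test_that("Cox estimates match grid maximization and tie methods agree when tie-free", {
  # 6-subject toy with Breslow ties
  sv <- survival_table(paste0("s", 1:6), time = c(2, 2, 3, 5, 5, 8),
                       event = c(1, 1, 1, 1, 0, 1),
                       x = c(1, 0, 1, 0, 1, 0))
  fit <- cox_fit(sv, "x", ties = "breslow")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, 0, time = sv$time, event = sv$event,
               x = sv$x)
  expect_equal(fit$table$beta, grid[which.max(ll)], tolerance = 1e-3)
  expect_gte(fit$loglik[2], fit$loglik[1])
  expect_true(fit$table$ci_low < fit$table$HR &
                fit$table$HR < fit$table$ci_high)

  # Efron == Breslow without tied event times
  set.seed(41)
  n <- 30
  sv2 <- survival_table(paste0("s", 1:n), time = rexp(n) + (1:n) * 1e-6,
                        event = rbinom(n, 1, 0.8), x = rnorm(n))
  fe <- cox_fit(sv2, "x", ties = "efron")
  fb <- cox_fit(sv2, "x", ties = "breslow")
  expect_equal(fe$table$beta, fb$table$beta, tolerance = 1e-9)

  expect_error(cox_fit(transform(sv, cst = 1), "cst"), "constant")
  expect_error(cox_fit(sv, "nope"), "not in")
})

test_that("a null covariate is estimated without bias at large n", {
  set.seed(55)
  n <- 1000
  sv <- survival_table(paste0("s", 1:n), time = rexp(n),
                       event = rbinom(n, 1, 0.8), x = rnorm(n))
  fit <- cox_fit(sv, "x")
  expect_lt(abs(fit$table$beta), 0.1)
  expect_gt(fit$table$p, 0.001)
})

test_that("forest tables preserve order and handle edge cases", {
  expect_equal(nrow(forest_table(list())), 0)
  sv <- survival_table(paste0("s", 1:20), time = rexp(20),
                       event = rbinom(20, 1, 0.8),
                       x = rnorm(20), y = rnorm(20))
  f1 <- cox_fit(sv, "x"); f2 <- cox_fit(sv, c("x", "y"))
  tab <- forest_table(list(uni = f1, multi = f2))
  expect_equal(tab$model, c("uni", "multi", "multi"))
  expect_equal(tab$term[1], "x")
  expect_true(all(tab$ci_low < tab$ci_high))
})

test_that("univariate-to-multivariate carry-over respects the inclusion rule", {
  set.seed(77)
  n <- 150
  z <- rnorm(n)
  rate <- 0.1 * exp(0.8 * z)
  sv <- survival_table(paste0("s", 1:n), time = rexp(n, rate),
                       event = rep(1, n), strong = z, noise = rnorm(n))
  co <- cox_carryover(sv, c("strong", "noise"))
  expect_true("strong" %in% co$carried)
  expect_false("noise" %in% co$carried)
  expect_equal(co$multivariate$table$term, "strong")
})
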