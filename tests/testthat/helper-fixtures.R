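# Shared fixtures and small independent oracles used across the suite.

# deterministic toy expression matrix
toy_expr <- function(n_genes = 6, n_samples = 5, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# adjusted Rand index from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  a_comb <- sum_comb(rowSums(tab))
  b_comb <- sum_comb(colSums(tab))
  expected <- a_comb * b_comb / choose(n, 2)
  max_idx <- (a_comb + b_comb) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}

# brute-force ssGSEA running sum, transcribed directly from the definition:
# rank genes within the sample (average ties), walk the descending order,
# accumulate weighted in-set and uniform out-of-set fractions
ssgsea_brute <- function(x, set_genes, alpha) {
  genes <- names(x)
  rnk <- rank(x, ties.method = "average")
  ord <- genes[order(rnk, decreasing = TRUE)]
  inset <- ord %in% set_genes
  w_total <- sum(rnk[ord[inset]]^alpha)
  n_miss <- length(genes) - sum(inset)
  p_hit <- 0; p_miss <- 0; es <- 0
  for (i in seq_along(ord)) {
    if (inset[i]) p_hit <- p_hit + rnk[ord[i]]^alpha / w_total
    else p_miss <- p_miss + 1 / n_miss
    es <- es + (p_hit - p_miss)
  }
  unname(es)
}

# brute-force BH step-up adjustment from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force 2-group log-rank chi-square, O-E/V transcription
logrank_brute <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d_idx]) -
      length(d_idx) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Greenwood-based standard error of S(t) at each event time, by hand
greenwood_se <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1; acc <- 0
  out <- data.frame(time = times, surv = NA_real_, se = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    if (n > d) acc <- acc + d / (n * (n - d)) else acc <- Inf
    out$surv[i] <- s
    out$se[i] <- if (is.finite(acc)) s * sqrt(acc) else 0
  }
  out
}

# small null cohort used by calibration tests
null_cohort <- function(n = 60, seed = 1) {
  generate_cohort(n_samples = n, n_genes = 12, n_regulators = 2,
                  delta = 0, program_size = 2, noise_sd = 1,
                  beta_surv = 0, seed = seed)
}
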