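# Kaplan-Meier estimation, log-rank testing, and Cox proportional-hazards
# fits, as thin tidy wrappers around the survival package.

#' Kaplan-Meier curves
#'
#' Product-limit estimate with Greenwood standard errors and log-transformed
#' 95% confidence intervals, overall or per group. The median is the first
#' time at which the survival step function drops to 0.5 or below (no
#' interpolation); a group with no events has a flat curve at 1 and an
#' undefined median (with a warning).
#'
#' @param surv a [survival_table()].
#' @param groups optional [group_assignment()] covering the samples.
#' @return named list of `km_curve` objects (one per group, or `"all"`),
#'   each a list: `table` (data.frame time, n_risk, n_event, survival,
#'   std_err, lower, upper), `median_survival` (NA if never reached),
#'   `n`, `n_events`.
#' @export
km_fit <- function(surv, groups = NULL) {
  if (sum(surv$event) < 1L) warning("no events in the survival table")
  lab <- if (is.null(groups)) rep("all", nrow(surv))
         else group_labels_for(groups, surv$sample_id)
  out <- lapply(split(seq_len(nrow(surv)), lab), function(idx) {
    s <- surv[idx, , drop = FALSE]
    if (sum(s$event) == 0L)
      warning("group with no events: survival curve is 1 everywhere")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = s,
                             conf.type = "log")
    sm <- summary(fit, censored = FALSE)
    tab <- data.frame(time = sm$time, n_risk = sm$n.risk,
                      n_event = sm$n.event, survival = sm$surv,
                      std_err = sm$std.err, lower = sm$lower,
                      upper = sm$upper)
    # Greenwood SE of S is S * sqrt(acc); once S hits 0 it is 0, not NaN
    tab$std_err[tab$survival == 0] <- 0
    med <- if (any(tab$survival <= 0.5)) min(tab$time[tab$survival <= 0.5])
           else NA_real_
    structure(list(table = tab, median_survival = med,
                   n = nrow(s), n_events = sum(s$event)),
              class = "km_curve")
  })
  out
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected chi-square with `#groups - 1` degrees of
#' freedom.
#'
#' @param surv a [survival_table()].
#' @param groups a [group_assignment()] with at least 2 groups.
#' @return list: `chi2`, `df`, `p`.
#' @export
logrank <- function(surv, groups) {
  lab <- group_labels_for(groups, surv$sample_id)
  if (length(unique(lab)) < 2L) stop("log-rank test needs at least 2 groups")
  if (sum(surv$event) < 1L) stop("log-rank test needs at least 1 event")
  d <- data.frame(time = surv$time, event = surv$event, g = lab)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- length(unique(lab)) - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ covariates` by partial-likelihood
#' Newton-Raphson (the survival package's coxph), Efron tie handling by
#' default (Breslow available for oracle comparability). Categorical
#' covariates are one-hot expanded by the model formula. Constant covariates
#' are rejected; coefficients beyond |beta| = 15 signal monotone-likelihood
#' separation and are capped with a warning.
#'
#' @param surv a [survival_table()] whose columns include `covariates`.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: data.frame `table` (term, beta, HR,
#'   se, z, p, ci_low, ci_high), `loglik` (null, fitted), `ties`, `n`,
#'   `n_events`, and the underlying `fit`.
#' @export
cox_fit <- function(surv, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  miss <- setdiff(covariates, names(surv))
  if (length(miss) > 0L)
    stop("covariate(s) not in survival table: ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (length(unique(surv[[cv]])) < 2L)
      stop("constant covariate: ", cv)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = as.data.frame(surv), ties = ties)
  beta <- stats::coef(fit)
  if (any(abs(beta) > 15)) {
    warning("possible monotone-likelihood separation: |beta| > 15 for ",
            paste(names(beta)[abs(beta) > 15], collapse = ", "),
            "; estimates capped at +/-15")
    beta <- pmin(pmax(beta, -15), 15)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    HR = exp(unname(beta)), se = unname(se),
                    z = unname(z),
                    p = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE),
                    ci_low = exp(unname(beta) - 1.96 * unname(se)),
                    ci_high = exp(unname(beta) + 1.96 * unname(se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik, ties = ties,
                 n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties, n = %d, events = %d)\n", x$ties, x$n,
              x$n_events))
  print(x$table, digits = 4)
  invisible(x)
}

#' Forest-plot table from Cox fits
#'
#' Binds the term tables of several fits into one tidy table (input order
#' preserved), the numeric backbone of a forest plot.
#'
#' @param fits list of `cox_fit` objects (possibly named by model).
#' @return data.frame: `model`, `term`, `HR`, `ci_low`, `ci_high`, `p`.
#' @export
forest_table <- function(fits) {
  if (length(fits) == 0L)
    return(data.frame(model = character(0), term = character(0),
                      HR = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0)))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model_", seq_along(fits))
  do.call(rbind, lapply(seq_along(fits), function(i) {
    tb <- fits[[i]]$table
    data.frame(model = nm[i], term = tb$term, HR = tb$HR,
               ci_low = tb$ci_low, ci_high = tb$ci_high, p = tb$p,
               stringsAsFactors = FALSE)
  }))
}

#' Univariate-to-multivariate Cox carry-over
#'
#' Fits each covariate univariately; covariates with univariate Wald p below
#' `alpha` enter one multivariate fit.
#'
#' @param surv a [survival_table()].
#' @param covariates candidate covariate names.
#' @param alpha univariate inclusion threshold (default 0.05).
#' @param ties tie handling, as in [cox_fit()].
#' @return list: `univariate` (named list of `cox_fit`), `multivariate`
#'   (`cox_fit` or NULL if nothing carried over), `carried` (names).
#' @export
cox_carryover <- function(surv, covariates, alpha = 0.05,
                          ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  uni <- lapply(covariates, function(cv) cox_fit(surv, cv, ties = ties))
  names(uni) <- covariates
  carried <- covariates[vapply(uni, function(f) min(f$table$p) < alpha, TRUE)]
  multi <- if (length(carried) >= 1L) cox_fit(surv, carried, ties = ties)
           else NULL
  list(univariate = uni, multivariate = multi, carried = carried)
}
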