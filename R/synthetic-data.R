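# Synthetic cohorts with the latent structure the analysis assumes: two
# modification patterns shifting a regulator panel, two correlated downstream
# gene programs ("immune", up in pattern 1; "stemness", up in pattern 2), and
# right-censored survival whose hazard depends on the latent pattern.

#' Generate a synthetic tumor cohort with known ground truth
#'
#' Samples split ~50/50 into two latent modification patterns. Regulator
#' genes get a mean shift of magnitude `delta` between patterns (means
#' +/- delta/2), with alternating shift direction across the panel
#' (odd-indexed regulators up in pattern 2, even-indexed down), emulating a
#' panel of both up- and down-regulated genes — a uniform-direction shift
#' would be invisible to correlation-based sample distances, which are
#' location-invariant across genes.
#' Each program has a per-sample latent factor `-delta*z + N(0,1)` (immune)
#' or `+delta*z + N(0,1)` (stemness), with `z = -1/2` (pattern 1) or `+1/2`
#' (pattern 2); program genes are factor plus `N(0, noise_sd)` noise, so they
#' are mutually correlated and pattern-associated. Remaining genes are pure
#' `N(0, noise_sd)` noise.
#'
#' @param n_samples number of samples (>= 4).
#' @param n_genes total genes (>= n_regulators + 2*program_size).
#' @param n_regulators size of the regulator panel.
#' @param delta mean expression shift of regulators (and programs) between
#'   patterns, in log-expression units.
#' @param program_size genes per program.
#' @param overlap_frac fraction of each program's genes shared with the other
#'   program (membership overlap; shared genes are driven by the immune
#'   factor and listed in both programs).
#' @param noise_sd residual SD around gene means.
#' @param beta_surv log-hazard coefficient linking the latent pattern
#'   (`z = +/- 1/2`) to the hazard; stored in the truth for
#'   [generate_survival()].
#' @param seed integer RNG seed; same seed gives bit-identical output.
#' @return list with `expr` (expression matrix) and `truth` (class
#'   `synthetic_truth`: `pattern`, `z`, `regulator_genes`,
#'   `regulator_effect` (signed per-regulator shift), `program_genes`,
#'   `delta`, `beta_surv`, `gene_ids`, `sample_ids`, `seed`).
#' @export
generate_cohort <- function(n_samples, n_genes, n_regulators = 21,
                            delta = 3, program_size = 50,
                            overlap_frac = 0, noise_sd = 1,
                            beta_surv = 0.7, seed = 1) {
  if (n_samples < 4L) stop("need n_samples >= 4")
  if (overlap_frac < 0 || overlap_frac > 1) stop("overlap_frac must be in [0,1]")
  n_shared <- floor(overlap_frac * program_size)
  n_program_genes <- 2L * program_size - n_shared
  if (n_genes < n_regulators + n_program_genes)
    stop("infeasible sizes: need n_genes >= n_regulators + program genes (",
         n_regulators + n_program_genes, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  pattern <- sample(rep(1:2, length.out = n_samples))
  z <- ifelse(pattern == 2L, 0.5, -0.5)

  reg_ids <- sprintf("REG%03d", seq_len(n_regulators))
  imm_only <- program_size - n_shared
  imm_ids <- sprintf("IMM%03d", seq_len(imm_only))
  shared_ids <- if (n_shared > 0) sprintf("SHRD%03d", seq_len(n_shared)) else character(0)
  stem_ids <- sprintf("STEM%03d", seq_len(program_size - n_shared))
  n_noise <- n_genes - n_regulators - n_program_genes
  noise_ids <- if (n_noise > 0) sprintf("GENE%04d", seq_len(n_noise)) else character(0)
  gene_ids <- c(reg_ids, imm_ids, shared_ids, stem_ids, noise_ids)

  x <- matrix(0, nrow = n_genes, ncol = n_samples,
              dimnames = list(gene_ids, sample_ids))
  # regulators: Normal(+/- delta/2, noise_sd) by pattern, alternating sign
  reg_sign <- rep_len(c(1, -1), n_regulators)
  x[reg_ids, ] <- outer(reg_sign * delta, z) +
    matrix(stats::rnorm(n_regulators * n_samples, sd = noise_sd), nrow = n_regulators)
  # program factors: shared across a program's genes within each sample
  f_imm <- -delta * z + stats::rnorm(n_samples)
  f_stem <- delta * z + stats::rnorm(n_samples)
  imm_all <- c(imm_ids, shared_ids)
  x[imm_all, ] <- matrix(rep(f_imm, each = length(imm_all)), nrow = length(imm_all)) +
    matrix(stats::rnorm(length(imm_all) * n_samples, sd = noise_sd),
           nrow = length(imm_all))
  x[stem_ids, ] <- matrix(rep(f_stem, each = length(stem_ids)), nrow = length(stem_ids)) +
    matrix(stats::rnorm(length(stem_ids) * n_samples, sd = noise_sd),
           nrow = length(stem_ids))
  if (n_noise > 0)
    x[noise_ids, ] <- matrix(stats::rnorm(n_noise * n_samples, sd = noise_sd),
                             nrow = n_noise)

  truth <- structure(list(
    pattern = stats::setNames(pattern, sample_ids),
    z = stats::setNames(z, sample_ids),
    regulator_genes = reg_ids,
    regulator_effect = stats::setNames(reg_sign * delta, reg_ids),
    program_genes = list(immune = c(imm_ids, shared_ids),
                         stemness = c(shared_ids, stem_ids)),
    delta = delta, beta_surv = beta_surv,
    gene_ids = gene_ids, sample_ids = sample_ids, seed = seed),
    class = "synthetic_truth")
  list(expr = x, truth = truth)
}

#' Generate right-censored survival for a synthetic cohort
#'
#' Event times are Exponential with rate
#' `baseline_hazard * exp(beta_surv * z)` where `z = +/- 1/2` by latent
#' pattern (proportional hazards by construction). Censoring times are
#' independent Exponential with the rate solved numerically so the expected
#' censored fraction equals `censor_rate`; `censor_rate = 0` leaves every
#' subject an event.
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param baseline_hazard positive baseline event rate.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a [survival_table()] with covariates `pattern` and `z`.
#' @export
generate_survival <- function(truth, baseline_hazard = 0.1,
                              censor_rate = 0.3, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0,1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- truth$z
  rate <- baseline_hazard * exp(truth$beta_surv * z)
  t_event <- stats::rexp(length(z), rate = rate)
  if (censor_rate == 0) {
    time <- t_event
    event <- rep(1L, length(z))
  } else {
    # P(censored | rate lambda_i, censor rate c) = c / (c + lambda_i)
    target <- function(c) mean(c / (c + rate)) - censor_rate
    c_rate <- stats::uniroot(target, lower = 1e-10,
                             upper = 1e6 * baseline_hazard)$root
    t_cens <- stats::rexp(length(z), rate = c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  survival_table(sample_id = names(z), time = time, event = event,
                 pattern = unname(truth$pattern), z = unname(z))
}

#' Generate gene-set signatures for a synthetic cohort
#'
#' One signature per true program (category `"program"`) plus decoy sets of
#' genes sampled uniformly from the cohort's gene universe (category
#' `"decoy"`).
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param n_decoy_sets number of decoy sets.
#' @param set_size genes per decoy set (<= number of genes).
#' @param seed integer RNG seed.
#' @return a [signature_set()].
#' @export
generate_signatures <- function(truth, n_decoy_sets = 5, set_size = 30,
                                seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (set_size > length(truth$gene_ids))
    stop("set_size exceeds number of genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sets <- truth$program_genes
  cat_lab <- rep("program", length(sets))
  if (n_decoy_sets > 0) {
    decoys <- lapply(seq_len(n_decoy_sets), function(i)
      sample(truth$gene_ids, set_size))
    names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoy_sets))
    sets <- c(sets, decoys)
    cat_lab <- c(cat_lab, rep("decoy", n_decoy_sets))
  }
  signature_set(sets, category = cat_lab, name = "synthetic_signatures")
}

#' Write a full synthetic cohort to disk
#'
#' Writes expression TSV, clinical TSV, regulator + program/decoy GMTs, and a
#' truth JSON next to each other.
#'
#' @param cohort list from [generate_cohort()].
#' @param surv a [survival_table()] for the cohort.
#' @param sigs a [signature_set()] for the cohort.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, surv, sigs, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    clinical = file.path(dir, paste0(prefix, "_clinical.tsv")),
    signatures = file.path(dir, paste0(prefix, "_signatures.gmt")),
    regulators = file.path(dir, paste0(prefix, "_regulators.gmt")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_expression(cohort$expr, paths[["expression"]])
  write_clinical(surv, paths[["clinical"]])
  write_gmt(sigs, paths[["signatures"]])
  write_gmt(signature_set(list(regulators = cohort$truth$regulator_genes),
                          category = "regulator_class"),
            paths[["regulators"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(pattern = as.list(truth$pattern), delta = truth$delta,
         beta_surv = truth$beta_surv, seed = truth$seed,
         regulator_genes = truth$regulator_genes,
         program_genes = truth$program_genes),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# save/restore the global RNG state so generators are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
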