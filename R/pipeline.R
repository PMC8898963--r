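# End-to-end orchestration: per cohort, consensus clustering on the
# regulator panel -> differential expression between the two clusters ->
# DEG calls; then cross-cohort signature intersection -> univariate-Cox
# prognostic filter on the training cohort -> PCA score model ->
# hazard-positive sign orientation -> scoring of every cohort -> median
# split -> survival and signature-association analyses. Every intermediate
# table is written to the output directory together with a JSON manifest
# sufficient to replay the run.

#' Assemble a pipeline configuration
#'
#' @param cohorts named list of cohorts; each cohort is a list with
#'   `expression` and `clinical` (file paths, or an in-memory matrix /
#'   [survival_table()]).
#' @param regulators regulator gene panel: a character vector, or a path to
#'   a one-set GMT.
#' @param signatures optional [signature_set()] (or GMT path) for the
#'   ssGSEA stage; `NULL` skips it.
#' @param training name of the training cohort for the score model
#'   (default: first cohort).
#' @param k_max largest consensus k swept (default 10).
#' @param n_resamples consensus resamples (default 1000).
#' @param sample_frac,gene_frac consensus subsampling fractions.
#' @param de_alpha,de_lfc DEG thresholds (defaults 0.05 and 1).
#' @param de_use_adjusted call DEGs on BH-adjusted p (default TRUE).
#' @param score_alpha prognostic-filter threshold (default 0.05).
#' @param refit_per_cohort re-standardize scores within each cohort rather
#'   than reusing the training X/SD (default FALSE).
#' @param ssgsea_alpha ssGSEA rank-weight exponent (default 0.25).
#' @param run_modules run the co-expression module stage on the training
#'   cohort's DEG submatrix (default FALSE).
#' @param merge_cut,min_module_size module-stage parameters.
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts, regulators, signatures = NULL,
                            training = names(cohorts)[1], k_max = 10,
                            n_resamples = 1000, sample_frac = 0.8,
                            gene_frac = 1, de_alpha = 0.05, de_lfc = 1,
                            de_use_adjusted = TRUE, score_alpha = 0.05,
                            refit_per_cohort = FALSE, ssgsea_alpha = 0.25,
                            run_modules = FALSE, merge_cut = 0.75,
                            min_module_size = 30, out_dir = tempfile("run"),
                            seed = 1) {
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list")
  if (!training %in% names(cohorts))
    stop("training cohort '", training, "' not among cohorts")
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    if (!all(c("expression", "clinical") %in% names(ch)))
      stop("cohort '", nm, "' needs 'expression' and 'clinical'")
    for (what in c("expression", "clinical")) {
      if (is.character(ch[[what]]) && !file.exists(ch[[what]]))
        stop("cohort '", nm, "' ", what, " file not found: ", ch[[what]])
    }
  }
  if (is.character(regulators) && length(regulators) == 1L &&
      grepl("\\.gmt$", regulators)) {
    if (!file.exists(regulators))
      stop("regulator GMT not found: ", regulators)
  }
  structure(mget(names(formals(pipeline_config))),
            class = "pipeline_config")
}

#' Run the full modification-pattern analysis
#'
#' Executes the staged analysis described in the package vignette and writes
#' every intermediate table (TSV) plus `manifest.json` under
#' `cfg$out_dir`. Stage errors abort with the stage name; outputs written
#' before the failure are retained.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible run report (list): per-cohort `selected_k`,
#'   `cluster_assignment`, `de_table`, `degs`, `scores`, `logrank`,
#'   `cox`, `ssgsea_tests`; plus `signature_genes`, `prognostic_genes`,
#'   `model`, `modules` (if requested), `manifest_path`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(df, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    utils::write.table(format(as.data.frame(df), digits = 10, trim = TRUE,
                              scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  outputs <- character(0)
  input_hashes <- list()

  # ---- load --------------------------------------------------------------
  cohorts <- stage("load", {
    lapply(names(cfg$cohorts), function(nm) {
      ch <- cfg$cohorts[[nm]]
      expr <- if (is.character(ch$expression)) {
        input_hashes[[paste0(nm, "_expression")]] <<-
          unname(tools::md5sum(ch$expression))
        read_expression(ch$expression)
      } else ch$expression
      surv <- if (is.character(ch$clinical)) {
        input_hashes[[paste0(nm, "_clinical")]] <<-
          unname(tools::md5sum(ch$clinical))
        read_clinical(ch$clinical)
      } else ch$clinical
      al <- align_samples(expr, surv)
      al
    })
  })
  names(cohorts) <- names(cfg$cohorts)
  regulators <- stage("load", {
    if (is.character(cfg$regulators) && length(cfg$regulators) == 1L &&
        grepl("\\.gmt$", cfg$regulators)) {
      input_hashes[["regulators"]] <- unname(tools::md5sum(cfg$regulators))
      unlist(read_gmt(cfg$regulators)$sets, use.names = FALSE)
    } else as.character(cfg$regulators)
  })
  sigs <- stage("load", {
    if (is.null(cfg$signatures)) NULL
    else if (is.character(cfg$signatures)) {
      input_hashes[["signatures"]] <- unname(tools::md5sum(cfg$signatures))
      read_gmt(cfg$signatures)
    } else cfg$signatures
  })

  report <- list(cohorts = list())

  # ---- per cohort: consensus clustering + DE -----------------------------
  for (i in seq_along(cohorts)) {
    nm <- names(cohorts)[i]
    co <- cohorts[[i]]
    seed_i <- substream_seed(cfg$seed, i)
    cons <- stage(paste0("consensus:", nm), {
      present <- intersect(regulators, rownames(co$expr))
      if (length(present) < 2L)
        stop("fewer than 2 regulator genes present in cohort '", nm, "'")
      consensus_sweep(co$expr, present,
                      ks = 2:cfg$k_max, n_resamples = cfg$n_resamples,
                      sample_frac = cfg$sample_frac,
                      gene_frac = cfg$gene_frac, seed = seed_i)
    })
    delta_tab <- cdf_and_delta(cons)
    selected_k <- select_k(delta_tab, k_max = cfg$k_max)
    # the downstream contrast is the two-cluster split (the pattern
    # dichotomy); the selected k is reported alongside
    assign2 <- cons[[1]]$assignment
    outputs <- c(outputs, tsv(delta_tab, paste0(nm, "_cdf_delta")),
                 tsv(assign2, paste0(nm, "_clusters")))
    de <- stage(paste0("diffexpr:", nm), de_test(co$expr, assign2))
    degs <- call_degs(de, alpha = cfg$de_alpha, lfc = cfg$de_lfc,
                      use_adjusted = cfg$de_use_adjusted)
    outputs <- c(outputs, tsv(de, paste0(nm, "_de_table")))
    report$cohorts[[nm]] <- list(selected_k = selected_k,
                                 delta_table = delta_tab,
                                 cluster_assignment = assign2,
                                 consensus = cons[[1]]$consensus,
                                 de_table = de, degs = degs)
  }

  # ---- cross-cohort signature -> prognostic filter -> score model --------
  deg_lists <- lapply(report$cohorts, function(x) as.character(x$degs))
  signature_genes <- stage("signature", Reduce(cross_cohort_signature, deg_lists))
  if (length(signature_genes) == 0L)
    stop("pipeline stage 'signature' failed: no cross-cohort overlap",
         call. = FALSE)
  tr <- cohorts[[cfg$training]]
  prog <- stage("prognostic_filter",
                prognostic_filter(signature_genes, tr$expr, tr$surv,
                                  alpha = cfg$score_alpha))
  outputs <- c(outputs, tsv(attr(prog, "cox_table"), "prognostic_filter"))
  model <- stage("score_model", {
    m <- fit_score_model(tr$expr, as.character(prog))
    sign_orient(m, tr$surv)
  })

  # ---- score every cohort, survival + associations -----------------------
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    sv <- stage(paste0("score:", nm),
                apply_score(model, co$expr,
                            restandardize = cfg$refit_per_cohort))
    groups <- group_assignment(sv$sample_id, sv$group)
    lr <- stage(paste0("survival:", nm), logrank(co$surv, groups))
    surv_sc <- co$surv
    surv_sc$m6ascore <- sv$score[match(surv_sc$sample_id, sv$sample_id)]
    cx <- stage(paste0("survival:", nm), cox_fit(surv_sc, "m6ascore"))
    outputs <- c(outputs, tsv(sv, paste0(nm, "_scores")),
                 tsv(cx$table, paste0(nm, "_score_cox")))
    report$cohorts[[nm]]$scores <- sv
    report$cohorts[[nm]]$logrank <- lr
    report$cohorts[[nm]]$cox <- cx
    if (!is.null(sigs)) {
      st <- stage(paste0("ssgsea:", nm), {
        sm <- floor_normalize(ssgsea_score(co$expr, sigs,
                                           alpha = cfg$ssgsea_alpha))
        list(by_cluster = group_score_test(
               sm, report$cohorts[[nm]]$cluster_assignment),
             by_score_group = group_score_test(sm, groups))
      })
      outputs <- c(outputs,
                   tsv(st$by_cluster, paste0(nm, "_ssgsea_by_cluster")),
                   tsv(st$by_score_group, paste0(nm, "_ssgsea_by_score")))
      report$cohorts[[nm]]$ssgsea_tests <- st
    }
  }

  # ---- optional co-expression modules on the training DEG submatrix ------
  if (isTRUE(cfg$run_modules)) {
    report$modules <- stage("modules", {
      degs_tr <- as.character(report$cohorts[[cfg$training]]$degs)
      sub <- tr$expr[degs_tr, , drop = FALSE]
      pw <- pick_soft_threshold(sub)
      mr <- detect_modules(sub, beta = pw$beta,
                           min_module_size = cfg$min_module_size,
                           merge_cut = cfg$merge_cut)
      traits <- matrix(model$train_scores[colnames(sub)], ncol = 1,
                       dimnames = list(colnames(sub), "m6ascore"))
      if (!is.null(mr$eigengenes)) mr <- module_trait(mr, traits)
      outputs <<- c(outputs, tsv(data.frame(gene = names(mr$module_of),
                                            module = mr$module_of),
                                 "modules"))
      list(beta = pw$beta, fit = pw$fit, result = mr)
    })
  }

  report$signature_genes <- signature_genes
  report$prognostic_genes <- as.character(prog)
  report$model <- model

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package = "m6apattern",
    version = as.character(utils::packageVersion("m6apattern")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed,
    parameters = cfg[c("training", "k_max", "n_resamples", "sample_frac",
                       "gene_frac", "de_alpha", "de_lfc", "de_use_adjusted",
                       "score_alpha", "refit_per_cohort", "ssgsea_alpha",
                       "run_modules", "merge_cut", "min_module_size")],
    cohorts = lapply(cfg$cohorts, function(ch)
      lapply(ch, function(x) if (is.character(x)) x else "<in-memory>")),
    regulators = if (is.character(cfg$regulators)) cfg$regulators
                 else "<in-memory>",
    signatures = if (is.null(cfg$signatures)) NULL
                 else if (is.character(cfg$signatures)) cfg$signatures
                 else "<in-memory>",
    input_hashes = input_hashes,
    outputs = basename(outputs),
    output_hashes = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                            basename(outputs))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  report$manifest_path <- manifest_path
  invisible(report)
}

#' Replay a pipeline run from its manifest
#'
#' Rebuilds the configuration from a `manifest.json` written by
#' [run_pipeline()] (file-path inputs only) and re-runs the pipeline into
#' `out_dir`.
#'
#' @param manifest_path path to a manifest.
#' @param out_dir output directory for the replay.
#' @return the replayed run report, invisibly.
#' @export
replay_pipeline <- function(manifest_path, out_dir = tempfile("replay")) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (any(unlist(man$cohorts) == "<in-memory>") ||
      identical(man$regulators, "<in-memory>"))
    stop("manifest records in-memory inputs; replay needs file paths")
  cohorts <- lapply(man$cohorts, function(ch)
    list(expression = ch$expression, clinical = ch$clinical))
  cfg <- do.call(pipeline_config, c(
    list(cohorts = cohorts, regulators = man$regulators,
         signatures = if (is.null(man$signatures) ||
                          identical(man$signatures, "<in-memory>")) NULL
                      else man$signatures,
         out_dir = out_dir, seed = man$seed),
    man$parameters))
  run_pipeline(cfg)
}
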