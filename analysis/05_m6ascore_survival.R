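#!/usr/bin/env Rscript
# Build the m6Ascore on the discovery cohort: univariate-Cox prognostic
# filter of the cross-cohort signature, correlation PCA, hazard-positive
# orientation; score both cohorts, median-split, and run the survival and
# association analyses.

library(m6apattern)
library(ggplot2)

data_dir <- "results/analysis/data"
sig_dir <- "results/analysis/signature"
out <- "results/analysis/score"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

signature <- readLines(file.path(sig_dir, "cross_cohort_signature.txt"))

load_cohort <- function(nm) {
  expr <- read_expression(file.path(data_dir, paste0(nm, "_expression.tsv")))
  surv <- read_clinical(file.path(data_dir, paste0(nm, "_clinical.tsv")))
  align_samples(expr, surv)
}
disc <- load_cohort("discovery")

prog <- prognostic_filter(signature, disc$expr, disc$surv, alpha = 0.05)
write.table(attr(prog, "cox_table"), file.path(out, "prognostic_filter.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(length(prog), " of ", length(signature),
        " signature genes pass the prognostic filter")

model <- sign_orient(fit_score_model(disc$expr, as.character(prog)),
                     disc$surv)

fits <- list()
for (nm in c("discovery", "validation")) {
  co <- if (nm == "discovery") disc else load_cohort(nm)
  sv <- apply_score(model, co$expr)
  write.table(sv, file.path(out, paste0(nm, "_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- group_assignment(sv$sample_id, sv$group)
  lr <- logrank(co$surv, groups)
  co$surv$m6ascore <- sv$score[match(co$surv$sample_id, sv$sample_id)]
  fits[[nm]] <- cox_fit(co$surv, "m6ascore")
  message(nm, ": high vs low log-rank chi2 = ", signif(lr$chi2, 4),
          ", p = ", signif(lr$p, 3), "; score HR = ",
          signif(fits[[nm]]$table$HR, 4))

  km <- km_fit(co$surv, groups)
  km_df <- do.call(rbind, lapply(names(km), function(g)
    data.frame(group = g, time = c(0, km[[g]]$table$time),
               surv = c(1, km[[g]]$table$survival))))
  p <- ggplot(km_df, aes(time, surv, color = group)) + geom_step() +
    labs(x = "time", y = "survival", title = paste(nm, "m6Ascore groups")) +
    theme_bw()
  ggsave(file.path(out, paste0(nm, "_km.pdf")), p, width = 6, height = 4)
}

write.table(forest_table(fits), file.path(out, "score_cox_forest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
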