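#!/usr/bin/env Rscript
# Quantify signature activity per sample with ssGSEA (0-floor normalized),
# compare program and decoy signatures between the two consensus clusters,
# and summarize per-category mean scores.

library(m6apattern)

data_dir <- "results/analysis/data"
cons_dir <- "results/analysis/consensus"
out <- "results/analysis/tme"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (nm in c("discovery", "validation")) {
  expr <- read_expression(file.path(data_dir, paste0(nm, "_expression.tsv")))
  sigs <- read_gmt(file.path(data_dir, paste0(nm, "_signatures.gmt")))
  sigs$category <- setNames(
    ifelse(grepl("^decoy", names(sigs$sets)), "decoy", "program"),
    names(sigs$sets))
  cl <- read.delim(file.path(cons_dir, paste0(nm, "_clusters_k2.tsv")))
  groups <- group_assignment(cl$sample_id, cl$label)

  sm <- floor_normalize(ssgsea_score(expr, sigs, alpha = 0.25))
  write.table(cbind(signature = rownames(sm), as.data.frame(sm)),
              file.path(out, paste0(nm, "_ssgsea.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tests <- group_score_test(sm, groups)
  write.table(tests, file.path(out, paste0(nm, "_cluster_tests.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig_prog <- sum(tests$q < 0.05 &
                      tests$signature %in% c("immune", "stemness"))
  n_sig_decoy <- sum(tests$q < 0.05 & grepl("^decoy", tests$signature))
  message(nm, ": ", n_sig_prog, "/2 program signatures and ", n_sig_decoy,
          "/5 decoys differ between clusters at q < 0.05")

  cat_means <- category_mean_scores(sm)
  write.table(cbind(category = rownames(cat_means), as.data.frame(cat_means)),
              file.path(out, paste0(nm, "_category_means.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
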