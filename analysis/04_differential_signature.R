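#!/usr/bin/env Rscript
# Dual-method differential expression between the consensus clusters in each
# cohort, DEG calling by the two-caller intersection, and the cross-cohort
# signature (genes differential in both cohorts).

library(m6apattern)

data_dir <- "results/analysis/data"
cons_dir <- "results/analysis/consensus"
out <- "results/analysis/signature"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

deg_lists <- list()
for (nm in c("discovery", "validation")) {
  expr <- read_expression(file.path(data_dir, paste0(nm, "_expression.tsv")))
  cl <- read.delim(file.path(cons_dir, paste0(nm, "_clusters_k2.tsv")))
  de <- de_test(expr, group_assignment(cl$sample_id, cl$label))
  write.table(de, file.path(out, paste0(nm, "_de_table.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  degs <- call_degs(de, alpha = 0.05, lfc = 1)
  deg_lists[[nm]] <- as.character(degs)
  dir_tab <- table(attr(degs, "direction"))
  message(nm, ": ", length(degs), " DEGs (",
          paste(names(dir_tab), dir_tab, sep = "=", collapse = ", "), ")")
}

signature <- cross_cohort_signature(deg_lists$discovery, deg_lists$validation)
writeLines(signature, file.path(out, "cross_cohort_signature.txt"))
message("cross-cohort signature: ", length(signature), " genes")
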